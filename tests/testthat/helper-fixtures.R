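# Fixture builders and independent oracles shared across test files.

# One fully specified call with overridable fields.
make_call <- function(chrom = "chr1", pos = 100L, ref = "C", alt = "T",
                      total_depth = 100L, alt_depth = 40L,
                      alt_fwd = NULL, alt_rev = NULL,
                      mq_pass_fraction = 1.0, variant_class = "snv",
                      splice_offset = NA_integer_,
                      population_maf = NA_real_, in_dbsnp = FALSE,
                      in_cosmic = FALSE, truth_label = NA_character_) {
  if (is.null(alt_fwd)) alt_fwd <- alt_depth %/% 2L
  if (is.null(alt_rev)) alt_rev <- alt_depth - alt_fwd
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             total_depth = as.integer(total_depth),
             alt_depth = as.integer(alt_depth),
             vaf = alt_depth / total_depth,
             alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
             mq_pass_fraction = mq_pass_fraction,
             variant_class = variant_class,
             splice_offset = as.integer(splice_offset),
             population_maf = population_maf, in_dbsnp = in_dbsnp,
             in_cosmic = in_cosmic, truth_label = truth_label,
             stringsAsFactors = FALSE)
}

make_calls <- function(...) {
  variant_calls(do.call(rbind, list(...)))
}

# Random but valid callset spanning all filter boundaries.
random_callset <- function(n, sample_id = "rand") {
  total <- sample(1:200, n, replace = TRUE)
  alt <- pmin(total, sample(0:30, n, replace = TRUE) +
                rbinom(n, total, 0.2))
  alt <- pmax(alt, 1L)
  fwd <- rbinom(n, alt, runif(n))
  cls <- sample(VARIANT_CLASSES, n, replace = TRUE)
  off <- ifelse(cls == "splice", sample(-5:5, n, replace = TRUE),
                NA_integer_)
  maf <- ifelse(runif(n) < 0.4, NA_real_, 10^runif(n, -6, -1))
  calls <- data.frame(
    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T"), n, TRUE),
    total_depth = as.integer(total), alt_depth = as.integer(alt),
    vaf = alt / total, alt_fwd = as.integer(fwd),
    alt_rev = as.integer(alt - fwd),
    mq_pass_fraction = round(runif(n, 0.8, 1), 4),
    variant_class = cls, splice_offset = off, population_maf = maf,
    in_dbsnp = runif(n) < 0.4, in_cosmic = runif(n) < 0.3,
    truth_label = NA_character_, stringsAsFactors = FALSE)
  calls <- calls[calls$ref != calls$alt, , drop = FALSE]
  calls <- calls[!duplicated(call_key(calls)), , drop = FALSE]
  sample_callset(sample_id, "assay", calls)
}

# Random panel of normals covering ~30% of a callset's keys.
random_pon <- function(calls, p_hit = 0.3) {
  hit <- calls[runif(nrow(calls)) < p_hit, , drop = FALSE]
  if (nrow(hit) == 0L) return(panel_of_normals(n_normals = 21L))
  entries <- do.call(rbind, lapply(seq_len(nrow(hit)), function(i) {
    k <- sample(1:3, 1)
    data.frame(chrom = hit$chrom[i], pos = hit$pos[i], ref = hit$ref[i],
               alt = hit$alt[i],
               normal_id = sprintf("n%02d", sample(1:21, k)),
               af = runif(k, 0.005, 0.6), stringsAsFactors = FALSE)
  }))
  panel_of_normals(entries, n_normals = 21L)
}

# Independent straight-line re-implementation of the filter cascade,
# evaluated one call at a time with explicit branching. Used only as an
# oracle; deliberately shares no code with apply_cascade().
oracle_pass_one <- function(call, pon_af_by_key, cfg) {
  # variant class
  cls_ok <- FALSE
  if (call$variant_class %in% c("snv", "indel", "frameshift",
                                "start_stop", "splice")) cls_ok <- TRUE
  if (call$variant_class == "synonymous" && cfg$include_synonymous)
    cls_ok <- TRUE
  # splice window
  spl_ok <- TRUE
  if (call$variant_class == "splice") {
    if (call$splice_offset > cfg$splice_window_bp ||
        call$splice_offset < -cfg$splice_window_bp) spl_ok <- FALSE
  }
  # population MAF
  maf_ok <- TRUE
  if (!is.na(call$population_maf)) {
    if (call$population_maf >= cfg$maf_threshold) maf_ok <- FALSE
  }
  # dbSNP unless COSMIC
  db_ok <- TRUE
  if (isTRUE(call$in_dbsnp) && !isTRUE(call$in_cosmic)) db_ok <- FALSE
  # read support and mapping quality
  sup_ok <- call$alt_depth >= cfg$min_alt_reads && call$vaf >= cfg$min_vaf
  mq_ok <- call$mq_pass_fraction >= cfg$min_mq_pass_fraction
  # panel of normals ratio
  pon_ok <- TRUE
  key <- paste0(call$chrom, ":", call$pos, ":", call$ref, ">", call$alt)
  afs <- pon_af_by_key[[key]]
  if (!is.null(afs)) {
    for (af in afs) {
      if (!(call$vaf / af > cfg$pon_ratio)) pon_ok <- FALSE
    }
  }
  c(class = cls_ok, splice = spl_ok, maf = maf_ok, dbsnp = db_ok,
    support = sup_ok, mq = mq_ok, pon = pon_ok)
}

oracle_cascade <- function(cs, pon, cfg) {
  rules <- c("class", "splice", "maf", "dbsnp", "support", "mq", "pon")
  calls <- cs$calls
  if (nrow(calls) == 0L)
    return(matrix(logical(0), 0, 7, dimnames = list(NULL, rules)))
  by_key <- split(pon$entries$af, call_key(pon$entries))
  t(vapply(seq_len(nrow(calls)), function(i)
    oracle_pass_one(calls[i, , drop = FALSE], by_key, cfg),
    logical(7)))
}

# Small uniform-coverage fixture over a single-interval territory.
uniform_coverage <- function(territory, depth, sample_id = "s") {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(territory)),
                   start = GenomicRanges::start(territory) - 1L,
                   end = GenomicRanges::end(territory))
  coverage_profile(df$chrom, df$start, df$end,
                   rep(depth, nrow(df)), territory, sample_id)
}

# Write a VCF text fixture; returns path.
write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header_fixture <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
  "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
  "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alt fwd\">",
  "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alt rev\">",
  "##INFO=<ID=MQPF,Number=1,Type=Float,Description=\"MQ pass fraction\">",
  "##INFO=<ID=CLASS,Number=A,Type=String,Description=\"Class\">",
  "##INFO=<ID=SPLOFF,Number=A,Type=Integer,Description=\"Splice offset\">",
  "##INFO=<ID=PMAF,Number=A,Type=Float,Description=\"Population MAF\">",
  "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP\">",
  "##INFO=<ID=COSMIC,Number=0,Type=Flag,Description=\"COSMIC\">",
  "##contig=<ID=chr1>",
  paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        sep = "\t"))
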