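#' Canonical INFO tag dialect
#'
#' Variant attributes arrive from heterogeneous vendor pipelines; the
#' package reads and writes one canonical dialect of INFO tags and foreign
#' VCFs are adapted by renaming tags here, not by code changes.
#'
#' Per-allele tags (`Number=A`) are comma lists parallel to ALT;
#' `allele_depths` is `Number=R` (reference first). `dbsnp` and `cosmic`
#' are flags.
#'
#' @param depth total read depth tag (Integer, 1). Required.
#' @param allele_depths per-allele read depths (Integer, R). Required.
#' @param alt_fwd,alt_rev strand-resolved alt read counts (Integer, A).
#' @param mq_pass_fraction fraction of reads with mapping quality > 1
#'   (Float, 1).
#' @param variant_class functional class annotation (String, A).
#' @param splice_offset signed bp distance to the nearest exon/intron
#'   boundary (Integer, A).
#' @param population_maf germline-resource minor allele fraction (Float, A).
#' @param dbsnp,cosmic database membership (Flag).
#' @param truth_label simulator provenance (String, A).
#' @return named list of tag names, class `tag_dialect`.
#' @export
tag_dialect <- function(depth = "DP", allele_depths = "AD",
                        alt_fwd = "SAF", alt_rev = "SAR",
                        mq_pass_fraction = "MQPF",
                        variant_class = "CLASS", splice_offset = "SPLOFF",
                        population_maf = "PMAF",
                        dbsnp = "DB", cosmic = "COSMIC",
                        truth_label = "TRUTH") {
  structure(list(depth = depth, allele_depths = allele_depths,
                 alt_fwd = alt_fwd, alt_rev = alt_rev,
                 mq_pass_fraction = mq_pass_fraction,
                 variant_class = variant_class,
                 splice_offset = splice_offset,
                 population_maf = population_maf,
                 dbsnp = dbsnp, cosmic = cosmic,
                 truth_label = truth_label),
            class = "tag_dialect")
}

.info_has_flag <- function(info, tag) {
  grepl(paste0("(^|;)", tag, "(;|$|=)"), info)
}

.split_field <- function(x, n_alt) {
  # x: character vector (one per record, comma lists or NA); returns list
  out <- strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
  Map(function(parts, n) {
    if (length(parts) == 0L) rep(NA_character_, n)
    else if (length(parts) == n) parts
    else .stopf("per-allele tag has %d values for %d alt allele(s)",
                length(parts), n)
  }, out, n_alt)
}

#' Read an annotated VCF into a sample callset
#'
#' Multi-allelic records are split into one call per alternate allele;
#' per-allele tags are distributed accordingly and the reference allele
#' depth is discarded. Optional tags missing from the file yield `NA`
#' fields, never defaults.
#'
#' @param path VCF 4.2 file (sites-only or with samples; only the fixed
#'   columns and INFO field are used).
#' @param dialect a [tag_dialect()].
#' @param sample_id,assay_id identifiers; default to the file name.
#' @param mode,matched_normal_id see [sample_callset()].
#' @return a [sample_callset()]; the per-call FILTER strings of the input
#'   are available as `attr(x$calls, "filter")`.
#' @export
read_vcf <- function(path, dialect = tag_dialect(),
                     sample_id = sub("\\.vcf$", "", basename(path)),
                     assay_id = sample_id, mode = "tumor_only",
                     matched_normal_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta_ids <- unlist(regmatches(v@meta,
                                regexec("^##INFO=<ID=([^,>]+)", v@meta)))
  header_tags <- meta_ids[!grepl("^##", meta_ids)]
  for (req in c("depth", "allele_depths")) {
    if (!(dialect[[req]] %in% header_tags))
      .stopf("required INFO tag '%s' (%s) missing from VCF header of %s",
             dialect[[req]], req, path)
  }
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L)
    return(sample_callset(sample_id, assay_id, variant_calls(), mode,
                          matched_normal_id))
  info <- fix[, "INFO"]
  has <- function(tag) tag %in% header_tags
  get1 <- function(tag) {
    if (!has(tag)) return(rep(NA_character_, nrow(fix)))
    as.character(vcfR::extract.info(v, element = tag))
  }
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  dp <- as.integer(get1(dialect$depth))
  ad <- .split_field(get1(dialect$allele_depths), n_alt + 1L)
  saf <- .split_field(get1(dialect$alt_fwd), n_alt)
  sar <- .split_field(get1(dialect$alt_rev), n_alt)
  cls <- .split_field(get1(dialect$variant_class), n_alt)
  spl <- .split_field(get1(dialect$splice_offset), n_alt)
  pmaf <- .split_field(get1(dialect$population_maf), n_alt)
  tru <- .split_field(get1(dialect$truth_label), n_alt)
  mqpf <- as.numeric(get1(dialect$mq_pass_fraction))
  db <- if (has(dialect$dbsnp)) .info_has_flag(info, dialect$dbsnp) else
    rep(NA, nrow(fix))
  cos <- if (has(dialect$cosmic)) .info_has_flag(info, dialect$cosmic) else
    rep(NA, nrow(fix))

  rec <- rep(seq_len(nrow(fix)), n_alt)
  aix <- unlist(lapply(n_alt, seq_len))
  pick <- function(lst, offset = 0L)
    unlist(Map(function(p, i) p[i + offset],
               lst[rec], aix), use.names = FALSE)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c(".", ""),
                                                        NA, x)))
  int <- function(x) suppressWarnings(as.integer(ifelse(x %in% c(".", ""),
                                                        NA, x)))
  alt_depth <- int(pick(ad, offset = 1L))
  if (anyNA(alt_depth))
    .stopf("missing per-allele depth (%s) in %s", dialect$allele_depths, path)
  chr <- function(x) ifelse(x %in% c(".", ""), NA_character_, x)
  calls <- data.frame(
    chrom = fix[rec, "CHROM"],
    pos = as.integer(fix[rec, "POS"]),
    ref = fix[rec, "REF"],
    alt = unlist(alts, use.names = FALSE),
    total_depth = dp[rec],
    alt_depth = alt_depth,
    vaf = alt_depth / dp[rec],
    alt_fwd = int(pick(saf)),
    alt_rev = int(pick(sar)),
    mq_pass_fraction = mqpf[rec],
    variant_class = chr(pick(cls)),
    splice_offset = int(pick(spl)),
    population_maf = num(pick(pmaf)),
    in_dbsnp = db[rec],
    in_cosmic = cos[rec],
    truth_label = chr(pick(tru)),
    stringsAsFactors = FALSE)
  filt <- fix[rec, "FILTER"]
  ord <- order(calls$chrom, calls$pos)
  calls <- variant_calls(calls[ord, , drop = FALSE])
  attr(calls, "filter") <- filt[ord]
  cs <- sample_callset(sample_id, assay_id, calls, mode, matched_normal_id)
  attr(cs$calls, "filter") <- filt[ord]
  cs
}

.FILTER_DESCRIPTIONS <- c(
  class = "variant class not counted towards mutational burden",
  splice = "splice variant outside the boundary window",
  maf = "population minor allele frequency at or above threshold",
  dbsnp = "dbSNP member absent from COSMIC",
  support = "insufficient alt read support or allelic fraction",
  mq = "insufficient fraction of reads with mapping quality > 1",
  pon = "allelic-fraction ratio to a panel normal at or below threshold")

.fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".", formatC(x, digits = digits, format = "g"))
}

#' Write a callset with filter verdicts as VCF 4.2
#'
#' Survivors get `FILTER=PASS`; others a semicolon-separated list of the
#' rule codes they failed. All canonical dialect tags present in the calls
#' are written, so the file round-trips through [read_vcf()].
#'
#' @param callset a [sample_callset()].
#' @param verdicts verdict table from [apply_cascade()], or `NULL` to
#'   write every call as PASS. Must cover every call.
#' @param path output file.
#' @param dialect a [tag_dialect()].
#' @param strand_flags optional logical vector (one per call) exported as
#'   an `SBFLAG` INFO tag marking strand-imbalanced calls.
#' @return `path`, invisibly.
#' @export
write_filtered_vcf <- function(callset, verdicts, path,
                               dialect = tag_dialect(),
                               strand_flags = NULL) {
  calls <- callset$calls
  if (is.null(verdicts)) {
    filt <- rep("PASS", nrow(calls))
  } else {
    idx <- match(call_key(calls), verdicts$key)
    if (anyNA(idx))
      .stopf("verdicts missing for %d call(s)", sum(is.na(idx)))
    filt <- ifelse(verdicts$passed[idx], "PASS", verdicts$failed_rules[idx])
  }
  d <- dialect
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##source=tmbpanel"),
            sprintf("##tmbpanel_sample=%s", callset$sample_id),
            sprintf("##tmbpanel_assay=%s", callset$assay_id),
            sprintf("##tmbpanel_mode=%s", callset$mode),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Total read depth\">", d$depth),
    sprintf("##INFO=<ID=%s,Number=R,Type=Integer,Description=\"Per-allele read depths\">", d$allele_depths),
    sprintf("##INFO=<ID=%s,Number=A,Type=Integer,Description=\"Alt reads on forward strand\">", d$alt_fwd),
    sprintf("##INFO=<ID=%s,Number=A,Type=Integer,Description=\"Alt reads on reverse strand\">", d$alt_rev),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Fraction of reads with mapping quality > 1\">", d$mq_pass_fraction),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Variant class\">", d$variant_class),
    sprintf("##INFO=<ID=%s,Number=A,Type=Integer,Description=\"Signed bp distance to exon/intron boundary\">", d$splice_offset),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Population minor allele fraction\">", d$population_maf),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"dbSNP membership\">", d$dbsnp),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"COSMIC membership\">", d$cosmic),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Simulation truth label\">", d$truth_label),
    "##INFO=<ID=SBFLAG,Number=0,Type=Flag,Description=\"Strand-imbalance flag\">",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", names(.FILTER_DESCRIPTIONS),
            .FILTER_DESCRIPTIONS),
    sprintf("##contig=<ID=%s>", unique(calls$chrom)))
  n <- nrow(calls)
  if (n > 0L) {
    info <- paste0(
      d$depth, "=", calls$total_depth,
      ";", d$allele_depths, "=", calls$total_depth - calls$alt_depth, ",",
      calls$alt_depth)
    opt <- function(tag, val, fmt = identity) {
      keep <- !is.na(val)
      ifelse(keep, paste0(";", tag, "=", fmt(val)), "")
    }
    info <- paste0(info,
      opt(d$alt_fwd, calls$alt_fwd),
      opt(d$alt_rev, calls$alt_rev),
      opt(d$mq_pass_fraction, calls$mq_pass_fraction, .fmt_num),
      opt(d$variant_class, calls$variant_class),
      opt(d$splice_offset, calls$splice_offset),
      opt(d$population_maf, calls$population_maf,
          function(x) .fmt_num(x, digits = 8)),
      ifelse(!is.na(calls$in_dbsnp) & calls$in_dbsnp, paste0(";", d$dbsnp), ""),
      ifelse(!is.na(calls$in_cosmic) & calls$in_cosmic,
             paste0(";", d$cosmic), ""),
      opt(d$truth_label, calls$truth_label))
    if (!is.null(strand_flags))
      info <- paste0(info, ifelse(strand_flags, ";SBFLAG", ""))
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  filt, info, sep = "\t")
  } else body <- character()
  writeLines(c(meta, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                           "FILTER", "INFO", sep = "\t"), body), path)
  invisible(path)
}
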