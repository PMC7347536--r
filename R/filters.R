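#' Filter cascade configuration
#'
#' Holds the thresholds of the somatic filter cascade. Defaults are the
#' published operating point: a +/- 2 bp splice window, a population minor
#' allele frequency gate of 0.01% (1e-4, strict `<`), at least 5
#' alt-supporting reads and an allelic fraction of 5% or more, at least
#' 90% of reads with mapping quality > 1, and a tumor/normal
#' allelic-fraction ratio that must strictly exceed 4 against every
#' normal carrying the variant.
#'
#' @param include_synonymous count coding synonymous variants? (default
#'   `FALSE`; both settings are analyzed downstream).
#' @param splice_window_bp half-width of the splice-site window in bp.
#' @param maf_threshold population MAF below which (strictly) a variant
#'   may pass.
#' @param min_alt_reads minimum alt-supporting reads (inclusive).
#' @param min_vaf minimum allelic fraction (inclusive).
#' @param min_mq_pass_fraction minimum fraction of reads with mapping
#'   quality > 1 (inclusive).
#' @param pon_ratio Af_tumor/Af_normal ratio that must be strictly
#'   exceeded for every normal in which the variant was detected.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(include_synonymous = FALSE, splice_window_bp = 2L,
                          maf_threshold = 1e-4, min_alt_reads = 5L,
                          min_vaf = 0.05, min_mq_pass_fraction = 0.90,
                          pon_ratio = 4.0) {
  stopifnot(isTRUE(include_synonymous) || isFALSE(include_synonymous),
            splice_window_bp >= 0, maf_threshold > 0, min_alt_reads > 0,
            min_vaf > 0, min_vaf < 1, min_mq_pass_fraction > 0,
            pon_ratio > 0)
  structure(list(include_synonymous = include_synonymous,
                 splice_window_bp = as.integer(splice_window_bp),
                 maf_threshold = maf_threshold,
                 min_alt_reads = as.integer(min_alt_reads),
                 min_vaf = min_vaf,
                 min_mq_pass_fraction = min_mq_pass_fraction,
                 pon_ratio = pon_ratio),
            class = "filter_config")
}

.as_calls <- function(v) {
  if (inherits(v, "sample_callset")) v$calls else as.data.frame(v)
}

#' Individual filter rules
#'
#' Each rule is vectorized over the rows of a calls data frame and returns
#' `TRUE` for calls that pass that rule, independently of all other rules.
#'
#' * `class_filter`: only SNVs, indels, frameshifts, start/stop and splice
#'   variants count; synonymous variants only when
#'   `cfg$include_synonymous`; class `other` never passes.
#' * `splice_filter`: splice variants must lie within
#'   `splice_window_bp` of the exon/intron boundary (absolute offset);
#'   non-splice classes pass vacuously.
#' * `maf_filter`: population MAF must be strictly below
#'   `maf_threshold`; a variant unseen in the resource (`NA`) passes.
#' * `dbsnp_cosmic_filter`: dbSNP members are removed unless also in
#'   COSMIC.
#' * `support_filter`: at least `min_alt_reads` alt reads, allelic
#'   fraction `>= min_vaf` and mapping-quality pass fraction
#'   `>= min_mq_pass_fraction` (all boundaries inclusive).
#' * `pon_filter`: the tumor/normal allelic-fraction ratio must strictly
#'   exceed `pon_ratio` for every normal carrying the variant; variants
#'   absent from all normals pass vacuously.
#'
#' @param v a [variant_calls()] data frame or [sample_callset()].
#' @param cfg a [filter_config()].
#' @param pon a [panel_of_normals()].
#' @return logical vector, one element per call.
#' @name filter_rules
NULL

#' @rdname filter_rules
#' @export
class_filter <- function(v, cfg = filter_config()) {
  calls <- .as_calls(v)
  cls <- calls$variant_class
  if (anyNA(cls) || length(bad <- setdiff(unique(cls), VARIANT_CLASSES)))
    .stopf("unknown or missing variant_class: %s",
           paste(c(if (anyNA(cls)) "NA", setdiff(unique(cls), VARIANT_CLASSES)),
                 collapse = ", "))
  cls %in% c("snv", "indel", "frameshift", "start_stop", "splice") |
    (cls == "synonymous" & cfg$include_synonymous)
}

#' @rdname filter_rules
#' @export
splice_filter <- function(v, cfg = filter_config()) {
  calls <- .as_calls(v)
  is_splice <- calls$variant_class %in% "splice"
  if (any(is_splice & is.na(calls$splice_offset)))
    .stopf("splice variant without splice_offset")
  !is_splice | (abs(calls$splice_offset) <= cfg$splice_window_bp &
                  !is.na(calls$splice_offset))
}

#' @rdname filter_rules
#' @export
maf_filter <- function(v, cfg = filter_config()) {
  calls <- .as_calls(v)
  maf <- calls$population_maf
  if (any(!is.na(maf) & (maf < 0 | maf > 1)))
    .stopf("population_maf outside [0,1]")
  is.na(maf) | maf < cfg$maf_threshold
}

#' @rdname filter_rules
#' @export
dbsnp_cosmic_filter <- function(v) {
  calls <- .as_calls(v)
  db <- calls$in_dbsnp %in% TRUE
  cos <- calls$in_cosmic %in% TRUE
  !(db & !cos)
}

#' @rdname filter_rules
#' @export
support_filter <- function(v, cfg = filter_config()) {
  calls <- .as_calls(v)
  if (anyNA(calls$alt_depth) || anyNA(calls$vaf) ||
      anyNA(calls$mq_pass_fraction))
    .stopf("support filter needs alt_depth, vaf and mq_pass_fraction")
  calls$alt_depth >= cfg$min_alt_reads & calls$vaf >= cfg$min_vaf &
    calls$mq_pass_fraction >= cfg$min_mq_pass_fraction
}

#' @rdname filter_rules
#' @export
pon_filter <- function(v, pon, cfg = filter_config()) {
  calls <- .as_calls(v)
  pon_min_ratio(calls, pon) > cfg$pon_ratio
}

#' Apply the full somatic filter cascade
#'
#' Evaluates all rules independently (no short-circuiting) so that every
#' verdict lists every rule a call failed. In paired mode the matched
#' normal's allelic fractions are merged into the panel of normals before
#' the ratio filter, which removes the patient's own germline variants.
#'
#' The read-support rule is split into two reportable codes: `support`
#' (alt reads and allelic fraction) and `mq` (mapping-quality fraction).
#'
#' @param cs a [sample_callset()] (or bare calls data frame).
#' @param pon a [panel_of_normals()]; `NULL` for an empty panel.
#' @param cfg a [filter_config()].
#' @param matched_normal optional matched-normal [sample_callset()];
#'   required when `cs$mode == "paired"`.
#' @return data frame with one row per call: `key`, `chrom`, `pos`,
#'   `ref`, `alt`, logical pass columns `class`, `splice`, `maf`,
#'   `dbsnp`, `support`, `mq`, `pon`, overall `passed`, and
#'   `failed_rules` (semicolon-joined codes, `""` when passed).
#' @export
apply_cascade <- function(cs, pon = NULL, cfg = filter_config(),
                          matched_normal = NULL) {
  calls <- .as_calls(cs)
  if (is.null(pon)) pon <- panel_of_normals()
  if (inherits(cs, "sample_callset") && cs$mode == "paired") {
    if (is.null(matched_normal))
      .stopf("paired-mode cascade requires the matched normal callset")
    pon <- pon_merge_normal(pon, matched_normal)
  }
  if (nrow(calls) > 0L &&
      (anyNA(calls$alt_depth) || anyNA(calls$vaf) ||
       anyNA(calls$mq_pass_fraction)))
    .stopf("cascade needs alt_depth, vaf and mq_pass_fraction on every call")
  rules <- data.frame(
    class = class_filter(calls, cfg),
    splice = splice_filter(calls, cfg),
    maf = maf_filter(calls, cfg),
    dbsnp = dbsnp_cosmic_filter(calls),
    support = calls$alt_depth >= cfg$min_alt_reads &
      calls$vaf >= cfg$min_vaf,
    mq = calls$mq_pass_fraction >= cfg$min_mq_pass_fraction,
    pon = pon_filter(calls, pon, cfg))
  passed <- Reduce(`&`, rules)
  failed <- character(nrow(calls))
  bad <- which(!passed)
  if (length(bad)) {
    m <- !as.matrix(rules[bad, , drop = FALSE])
    failed[bad] <- vapply(seq_along(bad), function(i)
      paste(colnames(m)[m[i, ]], collapse = ";"), "")
  }
  data.frame(key = call_key(calls), chrom = calls$chrom, pos = calls$pos,
             ref = calls$ref, alt = calls$alt, rules,
             passed = passed, failed_rules = failed,
             stringsAsFactors = FALSE)
}

#' Export a verdict audit table
#'
#' @param verdicts output of [apply_cascade()].
#' @param path TSV destination.
#' @export
write_verdicts <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
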