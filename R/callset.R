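#' Variant classes recognized by the filter cascade
#'
#' `snv` denotes a non-synonymous single-nucleotide substitution; `splice`
#' variants carry a signed `splice_offset` (bp to the nearest exon/intron
#' boundary); `other` covers everything the burden calculation excludes
#' (deep intronic, UTR, ...).
#'
#' @export
VARIANT_CLASSES <- c("snv", "indel", "frameshift", "start_stop",
                     "splice", "synonymous", "other")

.CALL_COLUMNS <- c("chrom", "pos", "ref", "alt", "total_depth", "alt_depth",
                   "vaf", "alt_fwd", "alt_rev", "mq_pass_fraction",
                   "variant_class", "splice_offset", "population_maf",
                   "in_dbsnp", "in_cosmic", "truth_label")

#' Construct and validate a table of variant calls
#'
#' One row per called alternate allele (multi-allelic records are split
#' upstream). Optional annotations that are genuinely unknown are `NA`:
#' `population_maf` of `NA` means the variant is unseen in the germline
#' resource, not that its frequency is zero.
#'
#' @param df data frame with (a subset of) the columns `chrom`, `pos`,
#'   `ref`, `alt`, `total_depth`, `alt_depth`, `vaf`, `alt_fwd`, `alt_rev`,
#'   `mq_pass_fraction`, `variant_class`, `splice_offset`,
#'   `population_maf`, `in_dbsnp`, `in_cosmic`, `truth_label`. Missing
#'   optional columns are added as `NA`.
#' @return validated data frame, sorted by (`chrom`, `pos`).
#' @export
variant_calls <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), total_depth = integer(),
                     alt_depth = integer(), vaf = double(),
                     alt_fwd = integer(), alt_rev = integer(),
                     mq_pass_fraction = double(), variant_class = character(),
                     splice_offset = integer(), population_maf = double(),
                     in_dbsnp = logical(), in_cosmic = logical(),
                     truth_label = character(), stringsAsFactors = FALSE)
    return(df)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "total_depth", "alt_depth")
  miss <- setdiff(required, names(df))
  if (length(miss))
    .stopf("variant calls missing required column(s): %s",
           paste(miss, collapse = ", "))
  if (!("vaf" %in% names(df)))
    df$vaf <- df$alt_depth / df$total_depth
  for (col in setdiff(.CALL_COLUMNS, names(df)))
    df[[col]] <- switch(col,
      alt_fwd = , alt_rev = , splice_offset = NA_integer_,
      mq_pass_fraction = , population_maf = NA_real_,
      in_dbsnp = , in_cosmic = NA,
      truth_label = NA_character_)
  df <- df[, .CALL_COLUMNS]
  df$pos <- as.integer(df$pos)
  validate_variant_calls(df)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' @rdname variant_calls
#' @export
validate_variant_calls <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$alt_depth > df$total_depth))
    .stopf("alt_depth exceeds total_depth for %d call(s)",
           sum(df$alt_depth > df$total_depth))
  sb <- !is.na(df$alt_fwd) & !is.na(df$alt_rev)
  if (any(sb & (df$alt_fwd + df$alt_rev != df$alt_depth)))
    .stopf("alt_fwd + alt_rev must equal alt_depth")
  bad_vaf <- abs(df$vaf - df$alt_depth / df$total_depth) > 1e-6
  if (any(bad_vaf[df$total_depth > 0]))
    .stopf("vaf inconsistent with alt_depth/total_depth")
  unknown <- setdiff(unique(df$variant_class), c(VARIANT_CLASSES, NA))
  if (length(unknown))
    .stopf("unknown variant_class value(s): %s", paste(unknown, collapse = ", "))
  if (any(df$variant_class %in% "splice" & is.na(df$splice_offset)))
    .stopf("splice variants must carry splice_offset")
  pm <- df$population_maf
  if (any(!is.na(pm) & (pm < 0 | pm > 1)))
    .stopf("population_maf outside [0,1]")
  if (anyDuplicated(call_key(df)))
    .stopf("duplicate (chrom,pos,ref,alt) keys in callset")
  invisible(df)
}

#' A sample's calls under one assay
#'
#' @param sample_id,assay_id identifiers (assay = panel or exome).
#' @param mode `"tumor_only"` or `"paired"`; paired requires
#'   `matched_normal_id`.
#' @param calls a [variant_calls()] data frame.
#' @param matched_normal_id id of the matched normal sample, if any.
#' @return an object of class `sample_callset`.
#' @export
sample_callset <- function(sample_id, assay_id, calls,
                           mode = c("tumor_only", "paired"),
                           matched_normal_id = NULL) {
  mode <- match.arg(mode)
  if (mode == "paired" && is.null(matched_normal_id))
    .stopf("paired mode requires matched_normal_id")
  calls <- variant_calls(calls)
  structure(list(sample_id = sample_id, assay_id = assay_id, mode = mode,
                 matched_normal_id = matched_normal_id, calls = calls),
            class = "sample_callset")
}

#' @export
print.sample_callset <- function(x, ...) {
  cat(sprintf("<sample_callset> %s / %s (%s): %d calls\n",
              x$sample_id, x$assay_id, x$mode, nrow(x$calls)))
  invisible(x)
}
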