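.SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# Pyrimidine-collapsed substitution class of single-base ref/alt pairs;
# NA for non-SNVs.
.substitution_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep(NA_character_, length(ref))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt &
    ref %in% names(comp) & alt %in% names(comp)
  r <- ref[snv]; a <- alt[snv]
  flip <- r %in% c("A", "G")
  r[flip] <- comp[r[flip]]; a[flip] <- comp[a[flip]]
  out[snv] <- paste0(r, ">", a)
  out
}

#' C:G>T:A transition ratio and substitution spectrum
#'
#' The fraction of passing variants that are C:G>T:A transitions (C>T on
#' either strand, pyrimidine-collapsed) is an established indicator of
#' FFPE deamination artifacts. Following the definition used here, the
#' denominator is all passing variants including indels; set
#' `snv_only = TRUE` to restrict it to SNVs.
#'
#' @param cs a [sample_callset()] (or calls data frame).
#' @param verdicts matching [apply_cascade()] verdicts; calls with
#'   `passed = TRUE` enter the summary.
#' @param vaf_bins optional increasing VAF breakpoints; the default bins
#'   are `[0,0.02) [0.02,0.05) [0.05,0.10) [0.10,1]`.
#' @param snv_only drop indels and other non-SNVs from the denominator?
#' @return list with `n_passing`, `counts` (named vector over the 6
#'   pyrimidine-collapsed classes), `transition_ratio` (`NA` when
#'   nothing passes), and `by_vaf` (per-bin n and ratio).
#' @export
transition_ratio <- function(cs, verdicts, vaf_bins = c(0, 0.02, 0.05,
                                                        0.10, 1),
                             snv_only = FALSE) {
  calls <- .as_calls(cs)
  idx <- match(call_key(calls), verdicts$key)
  if (anyNA(idx)) .stopf("verdicts do not cover the callset")
  keep <- verdicts$passed[idx]
  calls <- calls[keep, , drop = FALSE]
  sub <- .substitution_class(calls$ref, calls$alt)
  if (snv_only) {
    calls <- calls[!is.na(sub), , drop = FALSE]
    sub <- sub[!is.na(sub)]
  }
  counts <- table(factor(sub, levels = .SUBSTITUTION_CLASSES))
  ratio_of <- function(s, n) if (n == 0) NA_real_ else
    sum(s %in% "C>T") / n
  by_vaf <- NULL
  if (!is.null(vaf_bins)) {
    bin <- cut(calls$vaf, breaks = vaf_bins, right = FALSE,
               include.lowest = TRUE)
    by_vaf <- do.call(rbind, lapply(levels(bin), function(b) {
      i <- bin %in% b
      data.frame(vaf_bin = b, n = sum(i),
                 transition_ratio = ratio_of(sub[i], sum(i)),
                 stringsAsFactors = FALSE)
    }))
  }
  list(n_passing = nrow(calls),
       counts = stats::setNames(as.integer(counts), names(counts)),
       transition_ratio = ratio_of(sub, nrow(calls)),
       by_vaf = by_vaf)
}

#' Strand-imbalance flag
#'
#' Flags a variant whose alt reads are significantly skewed to one strand
#' by a two-sided exact binomial test of `alt_fwd` against a balanced
#' proportion of 0.5 at level `alpha`. This is a deliberately simple
#' diagnostic for deamination-type artifacts (which arise on one strand);
#' it is reported alongside the cascade and does not remove calls unless
#' explicitly requested by the caller.
#'
#' @param v a calls data frame/[sample_callset()], or an integer vector of
#'   forward-strand alt counts (then `alt_rev` must be given).
#' @param alt_rev reverse-strand alt counts when `v` is a vector.
#' @param alpha significance level (default 0.01).
#' @return logical vector; `TRUE` = strand-imbalanced.
#' @export
strand_imbalance_flag <- function(v, alt_rev = NULL, alpha = 0.01) {
  if (is.null(alt_rev)) {
    calls <- .as_calls(v)
    fwd <- calls$alt_fwd; rev <- calls$alt_rev
  } else {
    fwd <- v; rev <- alt_rev
  }
  if (anyNA(fwd) || anyNA(rev))
    .stopf("strand counts must be populated")
  n <- fwd + rev
  if (any(n == 0)) .stopf("strand flag undefined at zero alt depth")
  vapply(seq_along(n), function(i)
    stats::binom.test(fwd[i], n[i], p = 0.5)$p.value < alpha, logical(1))
}

#' VAF-cutoff sensitivity report
#'
#' Re-runs the cascade at each allelic-fraction cutoff and summarizes the
#' pass count, the C:G>T:A transition ratio and the fraction of passing
#' calls carrying a strand-imbalance flag. Lowering the cutoff (e.g. from
#' 5% to 2%) admits additional low-VAF calls, where FFPE artifacts
#' predominantly live.
#'
#' @param cs a [sample_callset()].
#' @param pon a [panel_of_normals()] (or `NULL`).
#' @param cfg base [filter_config()]; `min_vaf` is overridden per cutoff.
#' @param cutoffs numeric VAF cutoffs (default `c(0.02, 0.05)`).
#' @param matched_normal matched normal for paired mode.
#' @param alpha significance level of the strand flag.
#' @return data frame with one row per cutoff: `vaf_cutoff`, `n_pass`,
#'   `transition_ratio`, `strand_flag_fraction`.
#' @export
vaf_stratified_report <- function(cs, pon = NULL, cfg = filter_config(),
                                  cutoffs = c(0.02, 0.05),
                                  matched_normal = NULL, alpha = 0.01) {
  do.call(rbind, lapply(cutoffs, function(cut) {
    cfg_i <- cfg; cfg_i$min_vaf <- cut
    verdicts <- apply_cascade(cs, pon, cfg_i, matched_normal = matched_normal)
    tr <- transition_ratio(cs, verdicts, vaf_bins = NULL)
    calls <- .as_calls(cs)
    pass <- calls[verdicts$passed[match(call_key(calls), verdicts$key)], ,
                  drop = FALSE]
    flaggable <- !is.na(pass$alt_fwd) & !is.na(pass$alt_rev) &
      (pass$alt_fwd + pass$alt_rev) > 0
    frac <- if (!any(flaggable)) NA_real_ else
      mean(strand_imbalance_flag(pass[flaggable, , drop = FALSE],
                                 alpha = alpha))
    data.frame(vaf_cutoff = cut, n_pass = tr$n_passing,
               transition_ratio = tr$transition_ratio,
               strand_flag_fraction = frac, stringsAsFactors = FALSE)
  }))
}
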