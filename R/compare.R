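#' Pearson correlation with t-statistic p-value
#'
#' Computes the product-moment correlation between two TMB vectors and
#' converts it to a t-statistic, `t = r * sqrt((n-2)/(1-r^2))`, whose
#' two-sided p-value is taken from the t-distribution with `n - 2`
#' degrees of freedom. Perfect correlation (|r| = 1) yields `t = Inf`
#' and `p = 0`.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with
#'   non-zero variance.
#' @return list with `n`, `r`, `t`, `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) .stopf("correlation needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("degenerate input: zero variance")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(n = n, r = r, t = t, p = p)
}

#' Bonferroni correction
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param m family size; defaults to `length(p_values)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' Exome/panel conversion factor
#'
#' The factor that places panel TMB on the reference (exome) scale:
#' the mean reference TMB divided by the mean panel TMB over the same
#' samples. Multiplying the panel values by the factor equalizes the two
#' means exactly.
#'
#' @param reference_tmbs,panel_tmbs equal-length TMB vectors.
#' @return scalar conversion factor.
#' @export
conversion_factor <- function(reference_tmbs, panel_tmbs) {
  if (length(reference_tmbs) != length(panel_tmbs))
    .stopf("vectors must have equal length")
  m <- mean(panel_tmbs)
  if (!is.finite(m) || m <= 0)
    .stopf("degenerate input: non-positive mean panel TMB")
  mean(reference_tmbs) / m
}

#' High/low TMB classification agreement
#'
#' Classifies each sample as TMB-high when its value strictly exceeds
#' `cutoff` (default 10 v/mb). The reference vector defines truth; panel
#' values are first multiplied by the conversion `factor`. Reports the
#' contingency counts and overall, positive and negative percent
#' agreement. An agreement percentage with an empty denominator (e.g. PPA
#' with no reference-positive samples) is `NA`.
#'
#' @param reference_tmbs,panel_tmbs equal-length TMB vectors.
#' @param factor conversion factor applied to the panel values.
#' @param cutoff classification threshold in v/mb (strict `>`).
#' @return list with `factor`, `cutoff`, `tp`, `tn`, `fp`, `fn`, `opa`,
#'   `ppa`, `npa` (percentages).
#' @export
agreement <- function(reference_tmbs, panel_tmbs, factor = 1,
                      cutoff = 10) {
  if (length(reference_tmbs) != length(panel_tmbs))
    .stopf("vectors must have equal length")
  truth <- reference_tmbs > cutoff
  test <- factor * panel_tmbs > cutoff
  tp <- sum(truth & test); tn <- sum(!truth & !test)
  fp <- sum(!truth & test); fn <- sum(truth & !test)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(factor = factor, cutoff = cutoff, tp = tp, tn = tn, fp = fp, fn = fn,
       opa = pct(tp + tn, tp + tn + fp + fn),
       ppa = pct(tp, tp + fn),
       npa = pct(tn, tn + fp))
}

#' Ratio of passing synonymous to non-synonymous variants
#'
#' Computed on verdicts obtained with `include_synonymous = TRUE` (the
#' synonymous class is otherwise filtered and the ratio would always be
#' 0). `NA` when no non-synonymous variant passes.
#'
#' @param cs a [sample_callset()] (or calls data frame).
#' @param verdicts matching [apply_cascade()] verdicts.
#' @return scalar ratio.
#' @export
syn_nonsyn_ratio <- function(cs, verdicts) {
  calls <- .as_calls(cs)
  idx <- match(call_key(calls), verdicts$key)
  if (anyNA(idx)) .stopf("verdicts do not cover the callset")
  pass <- verdicts$passed[idx]
  n_syn <- sum(pass & calls$variant_class == "synonymous")
  n_non <- sum(pass & calls$variant_class != "synonymous")
  if (n_non == 0) return(NA_real_)
  n_syn / n_non
}
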