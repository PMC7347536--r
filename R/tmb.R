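#' Turn a pass count and callable territory into a TMB value
#'
#' TMB is the number of passing variants per callable megabase. When no
#' territory is callable the burden is undefined and reported as `NA`
#' (never 0), with a warning: an undersequenced sample has no burden
#' estimate, not a zero burden.
#'
#' @param n_pass number of variants surviving the filter cascade at
#'   callable loci.
#' @param callable_mb callable megabases from [callable_megabases()].
#' @param sample_id,assay_id,mode,include_synonymous metadata carried into
#'   the result row.
#' @param min_coverage coverage threshold used for the denominator.
#' @return one-row data frame: `sample_id`, `assay_id`, `mode`,
#'   `include_synonymous`, `n_variants`, `callable_mb`, `tmb`,
#'   `min_coverage`.
#' @export
compute_tmb <- function(n_pass, callable_mb, sample_id = NA_character_,
                        assay_id = NA_character_, mode = NA_character_,
                        include_synonymous = NA, min_coverage = 15L) {
  if (n_pass < 0 || callable_mb < 0)
    .stopf("n_pass and callable_mb must be non-negative")
  if (callable_mb == 0) {
    warning(sprintf("sample %s/%s: no callable territory, TMB undefined",
                    sample_id, assay_id), call. = FALSE)
    tmb <- NA_real_
  } else tmb <- n_pass / callable_mb
  data.frame(sample_id = sample_id, assay_id = assay_id, mode = mode,
             include_synonymous = include_synonymous,
             n_variants = as.integer(n_pass), callable_mb = callable_mb,
             tmb = tmb, min_coverage = as.integer(min_coverage),
             stringsAsFactors = FALSE)
}

#' Run the filter cascade and TMB calculation on one callset
#'
#' Applies [apply_cascade()], then counts passing variants whose locus is
#' callable (depth strictly above `min_coverage`) and inside the
#' territory, and divides by the callable megabases. Numerator and
#' denominator therefore live in the same coverage-conditioned universe.
#'
#' @param cs a [sample_callset()].
#' @param pon a [panel_of_normals()] (or `NULL`).
#' @param cov coverage profile `GRanges` for this sample/assay.
#' @param territory territory `GRanges` of the assay's coding space.
#' @param cfg a [filter_config()].
#' @param matched_normal matched-normal callset for paired mode.
#' @param min_coverage callable-depth threshold (strict `>`).
#' @return list with elements `result` (a [compute_tmb()] row) and
#'   `verdicts` (the cascade audit table, with a `counted` column marking
#'   calls in the TMB numerator).
#' @export
run_tmb <- function(cs, pon, cov, territory, cfg = filter_config(),
                    matched_normal = NULL, min_coverage = 15L) {
  verdicts <- apply_cascade(cs, pon, cfg, matched_normal = matched_normal)
  calls <- cs$calls
  if (nrow(calls) > 0L) {
    inside <- in_territory(calls, territory)
    depth <- rep(0, nrow(calls))
    if (any(inside))
      depth[inside] <- depth_at(cov, calls$chrom[inside], calls$pos[inside])
    counted <- verdicts$passed & inside & depth > min_coverage
  } else counted <- logical(0)
  verdicts$counted <- counted
  cmb <- callable_megabases(cov, territory, min_coverage)
  res <- compute_tmb(sum(counted), cmb, cs$sample_id, cs$assay_id, cs$mode,
                     cfg$include_synonymous, min_coverage)
  list(result = res, verdicts = verdicts)
}

#' Germline overhead of tumor-only calling
#'
#' Compares tumor-only and paired results for the same sample, assay and
#' synonymous setting: the excess variants surviving tumor-only filtering
#' estimate the residual germline contamination of the TMB value.
#'
#' @param tumor_only,paired one-row results from [compute_tmb()] /
#'   [run_tmb()].
#' @return one-row data frame with `sample_id`, `assay_id`,
#'   `include_synonymous`, `delta_variants` and `delta_tmb`.
#' @export
germline_overhead <- function(tumor_only, paired) {
  if (tumor_only$sample_id != paired$sample_id ||
      tumor_only$assay_id != paired$assay_id ||
      !identical(tumor_only$include_synonymous, paired$include_synonymous))
    .stopf("germline_overhead requires matching sample, assay and synonymous flag")
  data.frame(sample_id = tumor_only$sample_id,
             assay_id = tumor_only$assay_id,
             include_synonymous = tumor_only$include_synonymous,
             delta_variants = tumor_only$n_variants - paired$n_variants,
             delta_tmb = tumor_only$tmb - paired$tmb,
             stringsAsFactors = FALSE)
}
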