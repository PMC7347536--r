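#' Draw heterogeneous per-sample true TMB values for a cohort
#'
#' Log-normal around 8 v/mb (sd of log 0.8), emulating the wide spread of
#' burdens across tumor entities, including occasional hypermutated
#' samples. Deterministic given the configuration seed.
#'
#' @param cfg a [simulation_config()].
#' @param n_samples number of values.
#' @return numeric vector of true TMB values.
#' @export
draw_cohort_tmb <- function(cfg, n_samples) {
  .with_seed(.derive_seed(cfg$seed, "cohort_tmb"),
             rlnorm(n_samples, log(8), 0.8))
}

# run_tmb over both synonymous modes; returns rows + syn/nonsyn ratio.
.call_one <- function(cs, pon, cov, territory, base_cfg, matched_normal,
                      min_coverage) {
  rows <- list(); ratio <- NA_real_
  for (syn in c(FALSE, TRUE)) {
    cfg <- base_cfg; cfg$include_synonymous <- syn
    out <- run_tmb(cs, pon, cov, territory, cfg,
                   matched_normal = matched_normal,
                   min_coverage = min_coverage)
    rows[[length(rows) + 1L]] <- out$result
    if (syn) ratio <- syn_nonsyn_ratio(cs, out$verdicts)
  }
  list(rows = do.call(rbind, rows), syn_ratio = ratio)
}

#' Run the TMB pipeline over a simulated cohort
#'
#' For every sample and assay the cascade and burden calculation are run
#' with and without synonymous variants; the exome is additionally run in
#' paired mode for samples with a matched normal.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param base_cfg a [filter_config()]; its `include_synonymous` flag is
#'   overridden internally.
#' @param min_coverage callable-depth threshold (strict `>`).
#' @return list with `tmb` (one row per sample x assay x mode x
#'   synonymous setting) and `syn_ratio` (per sample x assay x mode
#'   synonymous/non-synonymous pass ratio).
#' @export
call_cohort <- function(cohort, base_cfg = filter_config(),
                        min_coverage = 15L) {
  tmb <- list(); ratios <- list()
  exome <- cohort$territories$exome
  for (s in cohort$samples) {
    sim <- s$sim
    add <- function(res, sample_id, assay_id, mode) {
      tmb[[length(tmb) + 1L]] <<- res$rows
      ratios[[length(ratios) + 1L]] <<- data.frame(
        sample_id = sample_id, assay_id = assay_id, mode = mode,
        syn_nonsyn_ratio = res$syn_ratio, stringsAsFactors = FALSE)
    }
    add(.call_one(sim$tumor, cohort$pon, sim$tumor_coverage, exome,
                  base_cfg, NULL, min_coverage),
        sim$sample_id, "exome", "tumor_only")
    if (!is.null(sim$normal)) {
      paired_cs <- sample_callset(sim$sample_id, "exome", sim$tumor$calls,
                                  "paired",
                                  matched_normal_id = sim$normal$sample_id)
      add(.call_one(paired_cs, cohort$pon, sim$tumor_coverage, exome,
                    base_cfg, sim$normal, min_coverage),
          sim$sample_id, "exome", "paired")
    }
    for (assay in names(s$panels)) {
      p <- s$panels[[assay]]
      add(.call_one(p$callset, cohort$pon, p$coverage,
                    cohort$territories$panels[[assay]], base_cfg, NULL,
                    min_coverage),
          sim$sample_id, assay, "tumor_only")
    }
  }
  list(tmb = do.call(rbind, tmb), syn_ratio = do.call(rbind, ratios))
}

.tmb_subset <- function(tmb, assay, mode, syn) {
  tmb[tmb$assay_id == assay & tmb$mode == mode &
        tmb$include_synonymous == syn, , drop = FALSE]
}

#' Cross-assay harmonization report
#'
#' For each panel assay and synonymous setting: Pearson correlation of
#' panel TMB to the reference exome TMB (non-synonymous, following the
#' convention that the reference point is always the matching exome
#' without synonymous variants), its t-statistic p-value with Bonferroni
#' correction over all rows of the report, the exome/panel conversion
#' factor, and OPA/PPA/NPA at the classification cutoff after factor
#' correction. Rows are ordered by decreasing correlation.
#'
#' @param called output of [call_cohort()].
#' @param reference `"exome_paired"`, `"exome_tumor_only"` or `"auto"`
#'   (paired when any paired exome rows exist).
#' @param cutoff TMB-high classification cutoff in v/mb (strict `>`).
#' @param min_shared minimum shared samples for an assay to be compared.
#' @return data frame report; attribute `"reference"` names the
#'   reference mode used.
#' @export
compare_cohort <- function(called, reference = "auto", cutoff = 10,
                           min_shared = 3L) {
  tmb <- called$tmb
  n_paired <- length(unique(tmb$sample_id[tmb$assay_id == "exome" &
                                            tmb$mode == "paired"]))
  ref_mode <- switch(reference,
    auto = if (n_paired >= min_shared) "paired" else "tumor_only",
    exome_paired = "paired",
    exome_tumor_only = "tumor_only",
    .stopf("unknown reference '%s'", reference))
  ref <- .tmb_subset(tmb, "exome", ref_mode, FALSE)
  if (nrow(ref) < min_shared)
    .stopf("fewer than %d reference samples", min_shared)
  assays <- setdiff(unique(tmb$assay_id), character(0))
  rows <- list()
  # when the exome itself is the reference, it is not also a comparator
  if (ref_mode == "tumor_only") assays <- setdiff(assays, "exome")
  for (assay in assays) {
    for (syn in c(FALSE, TRUE)) {
      panel <- .tmb_subset(tmb, assay, "tumor_only", syn)
      shared <- intersect(panel$sample_id, ref$sample_id)
      if (length(shared) < min_shared) {
        warning(sprintf("assay %s: only %d shared samples, skipped",
                        assay, length(shared)), call. = FALSE)
        next
      }
      x <- panel$tmb[match(shared, panel$sample_id)]
      y <- ref$tmb[match(shared, ref$sample_id)]
      ok <- !is.na(x) & !is.na(y)
      ct <- pearson_with_p(x[ok], y[ok])
      fac <- conversion_factor(y[ok], x[ok])
      ag <- agreement(y[ok], x[ok], factor = fac, cutoff = cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = assay, include_synonymous = syn, n = ct$n, r = ct$r,
        t = ct$t, p = ct$p, conversion_factor = fac,
        opa = ag$opa, ppa = ag$ppa, npa = ag$npa,
        tp = ag$tp, tn = ag$tn, fp = ag$fp, fn = ag$fn,
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  rep$p_bonferroni <- bonferroni(rep$p, m = nrow(rep))
  rep <- rep[order(-rep$r), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "reference") <- paste0("exome_", ref_mode)
  rep
}

#' Germline overhead across a cohort
#'
#' For every sample with both tumor-only and paired exome results,
#' computes the excess variants and excess TMB of tumor-only calling,
#' per synonymous setting.
#'
#' @param called output of [call_cohort()].
#' @return data frame of [germline_overhead()] rows.
#' @export
overhead_cohort <- function(called) {
  tmb <- called$tmb
  rows <- list()
  for (syn in c(FALSE, TRUE)) {
    to <- .tmb_subset(tmb, "exome", "tumor_only", syn)
    pa <- .tmb_subset(tmb, "exome", "paired", syn)
    shared <- intersect(to$sample_id, pa$sample_id)
    for (sid in shared)
      rows[[length(rows) + 1L]] <- germline_overhead(
        to[to$sample_id == sid, , drop = FALSE],
        pa[pa$sample_id == sid, , drop = FALSE])
  }
  do.call(rbind, rows)
}
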