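#' Write a simulated cohort as a self-contained directory
#'
#' Layout: `config.yaml` (generator configuration plus per-sample true
#' TMB and pairing), `territories/*.bed`, `pon.tsv`, `truth.tsv`, and
#' `samples/<id>/<assay>.vcf` + `<assay>.coverage.tsv` (plus
#' `normal.vcf`/`normal.coverage.tsv` for paired samples). All files are
#' plain text; rewriting the same cohort produces byte-identical output.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$cfg
  meta <- unclass(cfg)
  meta$panel_specs <- as.list(meta$panel_specs)
  meta$n_samples <- length(cohort$samples)
  meta$sample_tmb_true <- lapply(cohort$samples, function(s) s$tmb_true)
  meta$sample_paired <- lapply(cohort$samples,
                               function(s) !is.null(s$sim$normal))
  yaml::write_yaml(meta, file.path(dir, "config.yaml"))
  tdir <- file.path(dir, "territories")
  dir.create(tdir, showWarnings = FALSE)
  write_bed(cohort$territories$exome, file.path(tdir, "exome.bed"))
  for (nm in names(cohort$territories$panels))
    write_bed(cohort$territories$panels[[nm]],
              file.path(tdir, paste0(nm, ".bed")))
  utils::write.table(cohort$pon$entries, file.path(dir, "pon.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in cohort$samples) {
    sim <- s$sim
    sdir <- file.path(dir, "samples", sim$sample_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    write_filtered_vcf(sim$tumor, NULL, file.path(sdir, "exome.vcf"))
    write_coverage(sim$tumor_coverage,
                   file.path(sdir, "exome.coverage.tsv"))
    if (!is.null(sim$normal)) {
      write_filtered_vcf(sim$normal, NULL, file.path(sdir, "normal.vcf"))
      write_coverage(sim$normal_coverage,
                     file.path(sdir, "normal.coverage.tsv"))
    }
    for (assay in names(s$panels)) {
      write_filtered_vcf(s$panels[[assay]]$callset, NULL,
                         file.path(sdir, paste0(assay, ".vcf")))
      write_coverage(s$panels[[assay]]$coverage,
                     file.path(sdir, paste0(assay, ".coverage.tsv")))
    }
  }
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `simulated_cohort`-shaped list (configuration, territories,
#'   panel of normals, per-sample callsets/coverage, truth table).
#' @export
read_cohort <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  sample_tmb <- unlist(meta$sample_tmb_true)
  sample_paired <- unlist(meta$sample_paired)
  meta$n_samples <- NULL; meta$sample_tmb_true <- NULL
  meta$sample_paired <- NULL
  meta$panel_specs <- unlist(meta$panel_specs)
  cfg <- do.call(simulation_config, meta)
  tdir <- file.path(dir, "territories")
  exome <- read_bed(file.path(tdir, "exome.bed"), name = "exome")
  panel_files <- setdiff(list.files(tdir, pattern = "\\.bed$"), "exome.bed")
  panels <- lapply(panel_files, function(f)
    read_bed(file.path(tdir, f)))
  names(panels) <- sub("\\.bed$", "", panel_files)
  pon <- panel_of_normals(utils::read.table(file.path(dir, "pon.tsv"),
                                            header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE),
                          n_normals = cfg$n_normals_pon)
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  sids <- list.dirs(file.path(dir, "samples"), recursive = FALSE,
                    full.names = FALSE)
  samples <- lapply(seq_along(sids), function(i) {
    sid <- sids[i]
    sdir <- file.path(dir, "samples", sid)
    tumor <- read_vcf(file.path(sdir, "exome.vcf"), sample_id = sid,
                      assay_id = "exome")
    tcov <- read_coverage(file.path(sdir, "exome.coverage.tsv"), exome,
                          sample_id = sid)
    normal <- NULL; ncov <- NULL
    if (file.exists(file.path(sdir, "normal.vcf"))) {
      normal <- read_vcf(file.path(sdir, "normal.vcf"),
                         sample_id = paste0(sid, "_N"), assay_id = "exome")
      ncov <- read_coverage(file.path(sdir, "normal.coverage.tsv"), exome,
                            sample_id = paste0(sid, "_N"))
    }
    pns <- list()
    for (nm in names(panels)) {
      vf <- file.path(sdir, paste0(nm, ".vcf"))
      if (!file.exists(vf)) next
      pns[[nm]] <- list(
        callset = read_vcf(vf, sample_id = sid, assay_id = nm),
        coverage = read_coverage(file.path(sdir,
                                           paste0(nm, ".coverage.tsv")),
                                 panels[[nm]], sample_id = sid))
    }
    list(sim = list(sample_id = sid, tumor = tumor, normal = normal,
                    tumor_coverage = tcov, normal_coverage = ncov,
                    truth = truth[truth$sample_id == sid, , drop = FALSE]),
         panels = pns,
         tmb_true = if (length(sample_tmb)) sample_tmb[match(sid, sids)]
         else NA_real_)
  })
  names(samples) <- sids
  structure(list(cfg = cfg, territories = list(exome = exome,
                                               panels = panels),
                 pon = pon, samples = samples, truth = truth),
            class = "simulated_cohort")
}
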