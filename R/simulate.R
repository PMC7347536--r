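#' Configuration of the synthetic tumor/normal cohort generator
#'
#' The generator emulates the statistical structure of annotated
#' tumor/normal variant calls over an exome and coding-territory gene
#' panels: somatic variants at a true per-megabase rate, germline
#' heterozygous/homozygous variants (mostly database-known, a small
#' private fraction), FFPE-like strand-skewed low-VAF C:G>T:A artifacts,
#' negative-binomial depth variation, and a panel of normals sharing the
#' population's germline sites. All outputs are deterministic given
#' `seed`.
#'
#' @param seed integer master seed; every stream is derived from it.
#' @param exome_mb exome coding territory size in MB (default 35.9).
#' @param panel_specs named numeric vector of panel coding sizes in MB;
#'   defaults to the five studied panels (1.2, 1.24, 1.2, 1.1, 1.3).
#' @param tmb_true somatic mutations per coding megabase.
#' @param purity tumor cell fraction in (0, 1]; clonal heterozygous
#'   somatic VAF is centered on `purity/2`.
#' @param vaf_concentration Beta concentration of the somatic VAF model.
#' @param germline_het_per_exome expected germline coding variants per
#'   individual over the exome.
#' @param germline_private_fraction fraction of germline variants absent
#'   from the emulated dbSNP/population resource (default 0.03).
#' @param germline_hom_fraction odds of a germline variant being
#'   homozygous (VAF ~ 1) rather than heterozygous (default 1/3).
#' @param carrier_frequency probability that an individual (patient or
#'   panel normal) carries any given shared germline site.
#' @param artifact_rate_per_mb FFPE artifact calls per coding MB of the
#'   tumor callset (default 0.5).
#' @param artifact_strand_skew fraction of an artifact's alt reads on its
#'   dominant strand (default 0.95).
#' @param coverage_mean,coverage_dispersion negative-binomial depth model
#'   (`mu`, `size`) applied per exon and per assay.
#' @param syn_fraction fraction of coding variants that are synonymous.
#' @param n_normals_pon number of normals in the panel of normals.
#' @param cosmic_somatic_fraction,cosmic_germline_fraction probability of
#'   a COSMIC membership flag for somatic / known germline variants.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, exome_mb = 35.9,
                              panel_specs = c(thermo = 1.2,
                                              illumina = 1.24,
                                              neo = 1.2,
                                              agilent_custom = 1.1,
                                              qiagen = 1.3),
                              tmb_true = 10, purity = 0.8,
                              vaf_concentration = 20,
                              germline_het_per_exome = 6700L,
                              germline_private_fraction = 0.03,
                              germline_hom_fraction = 1 / 3,
                              carrier_frequency = 0.5,
                              artifact_rate_per_mb = 0.5,
                              artifact_strand_skew = 0.95,
                              coverage_mean = 120,
                              coverage_dispersion = 8,
                              syn_fraction = 0.25,
                              n_normals_pon = 21L,
                              cosmic_somatic_fraction = 0.15,
                              cosmic_germline_fraction = 0.02) {
  stopifnot(exome_mb > 0, all(panel_specs > 0), tmb_true >= 0,
            purity > 0, purity <= 1, germline_het_per_exome >= 0,
            germline_private_fraction >= 0, germline_private_fraction <= 1,
            artifact_rate_per_mb >= 0,
            artifact_strand_skew >= 0, artifact_strand_skew <= 1,
            coverage_mean > 0, coverage_dispersion > 0,
            syn_fraction >= 0, syn_fraction <= 1, n_normals_pon >= 0)
  if (any(panel_specs > exome_mb))
    .stopf("panel coding size exceeds the exome")
  cfg <- list(seed = as.integer(seed), exome_mb = exome_mb,
              panel_specs = panel_specs, tmb_true = tmb_true,
              purity = purity, vaf_concentration = vaf_concentration,
              germline_het_per_exome = germline_het_per_exome,
              germline_private_fraction = germline_private_fraction,
              germline_hom_fraction = germline_hom_fraction,
              carrier_frequency = carrier_frequency,
              artifact_rate_per_mb = artifact_rate_per_mb,
              artifact_strand_skew = artifact_strand_skew,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              syn_fraction = syn_fraction,
              n_normals_pon = as.integer(n_normals_pon),
              cosmic_somatic_fraction = cosmic_somatic_fraction,
              cosmic_germline_fraction = cosmic_germline_fraction)
  class(cfg) <- "simulation_config"
  cfg
}

# -- internal building blocks -------------------------------------------------

.SPECTRUM_PROBS <- c("C>A" = 0.10, "C>G" = 0.08, "C>T" = 0.40,
                     "T>A" = 0.10, "T>C" = 0.22, "T>G" = 0.10)

# Draw (ref, alt) base pairs from the pyrimidine-collapsed substitution
# spectrum, then flip half of them to the purine strand representation.
.draw_substitutions <- function(n) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cls <- sample(names(.SPECTRUM_PROBS), n, replace = TRUE,
                prob = .SPECTRUM_PROBS)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  flip <- runif(n) < 0.5
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  list(ref = ref, alt = alt)
}

.draw_indel_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  anchor <- sample(bases, n, replace = TRUE)
  extra <- sample(bases, n, replace = TRUE)
  ins <- runif(n) < 0.5
  list(ref = ifelse(ins, anchor, paste0(anchor, extra)),
       alt = ifelse(ins, paste0(anchor, extra), anchor))
}

# Sample n positions uniformly over a territory, weighted by exon width.
.sample_positions <- function(n, gr) {
  w <- GenomicRanges::width(gr)
  idx <- sample.int(length(gr), n, replace = TRUE, prob = w)
  pos <- GenomicRanges::start(gr)[idx] +
    floor(runif(n) * w[idx])
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[idx],
             pos = as.integer(pos), exon = idx, stringsAsFactors = FALSE)
}

# Shared germline site pool: deterministic given cfg$seed and the exome.
.germline_pool <- function(cfg, exome) {
  n_known <- round(cfg$germline_het_per_exome *
                     (1 - cfg$germline_private_fraction))
  pool_n <- round(n_known / cfg$carrier_frequency)
  .with_seed(.derive_seed(cfg$seed, "germline_pool"), {
    loc <- .sample_positions(pool_n, exome)
    sub <- .draw_substitutions(pool_n)
    data.frame(loc[, c("chrom", "pos", "exon")],
               ref = sub$ref, alt = sub$alt,
               variant_class = ifelse(runif(pool_n) < cfg$syn_fraction,
                                      "synonymous", "snv"),
               maf = 10^runif(pool_n, -3, -0.4),
               stringsAsFactors = FALSE)
  })
}

.nb_depth <- function(n, cfg) {
  rnbinom(n, size = cfg$coverage_dispersion, mu = cfg$coverage_mean)
}

.coverage_from_depths <- function(gr, depth, sample_id, name) {
  prof <- gr
  S4Vectors::mcols(prof) <- NULL
  prof$depth <- as.numeric(depth)
  S4Vectors::metadata(prof)$sample_id <- sample_id
  S4Vectors::metadata(prof)$territory_name <- name
  prof
}

# -- territories --------------------------------------------------------------

#' Simulate exome and panel territories
#'
#' The exome is a chain of exon-like intervals (log-normal lengths,
#' median 150 bp) over 22 chromosomes totalling `exome_mb`; each panel is
#' a random subset of whole exome intervals totalling its configured
#' coding size to within 1%.
#'
#' @param cfg a [simulation_config()].
#' @return list with `exome` (territory `GRanges`) and `panels` (named
#'   list of territory `GRanges`).
#' @export
simulate_territories <- function(cfg) {
  .with_seed(.derive_seed(cfg$seed, "territories"), {
    target <- cfg$exome_mb * 1e6
    n_guess <- ceiling(target / 150) + 1000L
    len <- pmax(20L, as.integer(round(rlnorm(n_guess, log(150), 0.6))))
    keep <- which(cumsum(as.numeric(len)) >= target)[1]
    if (is.na(keep)) .stopf("internal: exon draw too small")
    len <- len[seq_len(keep)]
    n <- length(len)
    gap <- as.integer(round(rexp(n, 1 / 2000))) + 50L
    chrom <- paste0("chr", cut(seq_len(n), 22, labels = FALSE))
    # lay exons sequentially within each chromosome, separated by gaps
    df <- data.frame(chrom = chrom, len = len, gap = gap,
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom), , drop = FALSE]
    df$start0 <- unlist(lapply(split(seq_len(n), df$chrom), function(ix) {
      as.integer(cumsum(as.numeric(df$gap[ix])) +
                   c(0, cumsum(as.numeric(df$len[ix])))[seq_along(ix)])
    }), use.names = FALSE)
    exome <- territory(df$chrom, df$start0, df$start0 + df$len,
                       name = "exome")
    widths <- as.numeric(GenomicRanges::width(exome))
    panels <- lapply(seq_along(cfg$panel_specs), function(i) {
      tgt <- cfg$panel_specs[[i]] * 1e6
      perm <- sample.int(length(exome))
      take <- perm[cumsum(widths[perm]) <= tgt]
      # greedy refill so the panel lands within 1% of its target size
      remaining <- setdiff(perm, take)
      repeat {
        shortfall <- tgt - sum(widths[take])
        cand <- remaining[widths[remaining] <= shortfall]
        if (shortfall <= 0.002 * tgt || length(cand) == 0L) break
        add <- cand[cumsum(widths[cand]) <= shortfall]
        if (length(add) == 0L) add <- cand[1]
        take <- c(take, add)
        remaining <- setdiff(remaining, add)
      }
      sub <- GenomicRanges::sort(exome[take])
      S4Vectors::metadata(sub)$territory_name <- names(cfg$panel_specs)[i]
      sub
    })
    names(panels) <- names(cfg$panel_specs)
    list(exome = exome, panels = panels)
  })
}

# -- panel of normals ---------------------------------------------------------

#' Simulate the panel of normals
#'
#' Each normal carries the shared germline pool sites at the configured
#' carrier frequency, with binomially re-sampled allelic fractions and
#' negative-binomial depths, plus a small amount of per-normal noise at
#' random positions.
#'
#' @param cfg a [simulation_config()].
#' @param territories output of [simulate_territories()].
#' @return a [panel_of_normals()].
#' @export
simulate_pon <- function(cfg, territories) {
  pool <- .germline_pool(cfg, territories$exome)
  .with_seed(.derive_seed(cfg$seed, "pon"), {
    entries <- lapply(seq_len(cfg$n_normals_pon), function(j) {
      carries <- runif(nrow(pool)) < cfg$carrier_frequency
      site <- pool[carries, , drop = FALSE]
      nj <- nrow(site)
      truevaf <- ifelse(runif(nj) < cfg$germline_hom_fraction, 1, 0.5)
      depth <- .nb_depth(nj, cfg)
      alt <- rbinom(nj, depth, truevaf)
      ok <- depth > 0 & alt > 0
      germ <- data.frame(chrom = site$chrom[ok], pos = site$pos[ok],
                         ref = site$ref[ok], alt = site$alt[ok],
                         normal_id = sprintf("pon_normal_%02d", j),
                         af = alt[ok] / depth[ok],
                         stringsAsFactors = FALSE)
      n_noise <- rpois(1, 30)
      noise_loc <- .sample_positions(n_noise, territories$exome)
      noise_sub <- .draw_substitutions(n_noise)
      noise <- data.frame(chrom = noise_loc$chrom, pos = noise_loc$pos,
                          ref = noise_sub$ref, alt = noise_sub$alt,
                          normal_id = sprintf("pon_normal_%02d", j),
                          af = runif(n_noise, 0.02, 0.2),
                          stringsAsFactors = FALSE)
      rbind(germ, noise)
    })
    panel_of_normals(do.call(rbind, entries),
                     n_normals = cfg$n_normals_pon)
  })
}

# -- one sample ---------------------------------------------------------------

# Realize observed calls (depth, alt reads, strand split, mq) for a table
# of true variants at the exons of a coverage profile.
.realize_calls <- function(tab, depths, cfg) {
  n <- nrow(tab)
  if (n == 0L) {
    out <- tab
    out$total_depth <- integer(0); out$alt_depth <- integer(0)
    return(out)
  }
  depth <- depths[tab$exon]
  alt <- rbinom(n, depth, tab$true_vaf)
  keep <- depth > 0 & alt > 0
  tab <- tab[keep, , drop = FALSE]
  depth <- depth[keep]; alt <- alt[keep]
  n <- nrow(tab)
  skew <- ifelse(tab$truth_label == "artifact",
                 ifelse(runif(n) < 0.5, cfg$artifact_strand_skew,
                        1 - cfg$artifact_strand_skew),
                 0.5)
  fwd <- rbinom(n, alt, skew)
  tab$total_depth <- as.integer(depth)
  tab$alt_depth <- as.integer(alt)
  tab$vaf <- alt / depth
  tab$alt_fwd <- as.integer(fwd)
  tab$alt_rev <- as.integer(alt - fwd)
  tab$mq_pass_fraction <- rbeta(n, 60, 1)
  tab
}

# True-variant tables (before read-level realization) for one patient.
.draw_patient_variants <- function(cfg, territories, tmb_true) {
  exome <- territories$exome
  mb <- coding_mb(exome)
  pool <- .germline_pool(cfg, exome)

  # germline: shared (database-known) + private sites
  carries <- runif(nrow(pool)) < cfg$carrier_frequency
  known <- pool[carries, , drop = FALSE]
  n_known <- nrow(known)
  n_priv <- rpois(1, cfg$germline_het_per_exome *
                    cfg$germline_private_fraction)
  priv_loc <- .sample_positions(n_priv, exome)
  priv_sub <- .draw_substitutions(n_priv)
  germ <- data.frame(
    chrom = c(known$chrom, priv_loc$chrom),
    pos = c(known$pos, priv_loc$pos),
    exon = c(known$exon, priv_loc$exon),
    ref = c(known$ref, priv_sub$ref),
    alt = c(known$alt, priv_sub$alt),
    variant_class = c(known$variant_class,
                      ifelse(runif(n_priv) < cfg$syn_fraction,
                             "synonymous", "snv")),
    splice_offset = rep(NA_integer_, n_known + n_priv),
    population_maf = c(known$maf, rep(NA_real_, n_priv)),
    in_dbsnp = c(rep(TRUE, n_known), rep(FALSE, n_priv)),
    in_cosmic = c(runif(n_known) < cfg$cosmic_germline_fraction,
                  rep(FALSE, n_priv)),
    truth_label = rep("germline", n_known + n_priv),
    private = c(rep(FALSE, n_known), rep(TRUE, n_priv)),
    stringsAsFactors = FALSE)
  germ$true_vaf <- ifelse(runif(nrow(germ)) < cfg$germline_hom_fraction,
                          1, 0.5)

  # somatic: uniform over the exome at rate tmb_true per MB
  n_som <- rpois(1, tmb_true * mb)
  som_loc <- .sample_positions(n_som, exome)
  syn <- runif(n_som) < cfg$syn_fraction
  nonsyn_class <- sample(c("snv", "indel", "frameshift", "splice",
                           "start_stop"), n_som, replace = TRUE,
                         prob = c(0.85, 0.05, 0.05, 0.03, 0.02))
  cls <- ifelse(syn, "synonymous", nonsyn_class)
  som_sub <- .draw_substitutions(n_som)
  indel_like <- cls %in% c("indel", "frameshift")
  if (any(indel_like)) {
    ind <- .draw_indel_alleles(sum(indel_like))
    som_sub$ref[indel_like] <- ind$ref
    som_sub$alt[indel_like] <- ind$alt
  }
  m <- cfg$purity / 2
  som <- data.frame(
    chrom = som_loc$chrom, pos = som_loc$pos, exon = som_loc$exon,
    ref = som_sub$ref, alt = som_sub$alt, variant_class = cls,
    splice_offset = ifelse(cls == "splice",
                           sample(-2:2, n_som, replace = TRUE),
                           NA_integer_),
    population_maf = rep(NA_real_, n_som),
    in_dbsnp = rep(FALSE, n_som),
    in_cosmic = runif(n_som) < cfg$cosmic_somatic_fraction,
    truth_label = rep("somatic", n_som), private = rep(NA, n_som),
    true_vaf = rbeta(n_som, cfg$vaf_concentration * m,
                     cfg$vaf_concentration * (1 - m)),
    stringsAsFactors = FALSE)

  # FFPE-like artifacts: low-VAF strand-skewed C:G>T:A, tumor only
  n_art <- rpois(1, cfg$artifact_rate_per_mb * mb)
  art_loc <- .sample_positions(n_art, exome)
  gflip <- runif(n_art) < 0.5
  art <- data.frame(
    chrom = art_loc$chrom, pos = art_loc$pos, exon = art_loc$exon,
    ref = ifelse(gflip, "G", "C"), alt = ifelse(gflip, "A", "T"),
    variant_class = ifelse(runif(n_art) < cfg$syn_fraction,
                           "synonymous", "snv"),
    splice_offset = rep(NA_integer_, n_art),
    population_maf = rep(NA_real_, n_art),
    in_dbsnp = rep(FALSE, n_art), in_cosmic = rep(FALSE, n_art),
    truth_label = rep("artifact", n_art), private = rep(NA, n_art),
    true_vaf = runif(n_art, 0.01, 0.06),
    stringsAsFactors = FALSE)

  all <- rbind(germ, som, art)
  all[!duplicated(paste0(all$chrom, ":", all$pos, ":", all$ref, ">",
                         all$alt)), , drop = FALSE]
}

#' Simulate one tumor (and optionally matched normal) exome sample
#'
#' Draws the patient's true somatic, germline and artifact variants, then
#' realizes observed calls under per-exon negative-binomial depths:
#' `alt_depth ~ Binomial(depth, true VAF)`; variants with zero observed
#' alt reads are not emitted (a caller would not report them). Artifacts
#' appear only in the tumor; the matched normal carries the germline
#' variants re-sampled under its own coverage profile.
#'
#' @param cfg a [simulation_config()].
#' @param territories output of [simulate_territories()].
#' @param sample_id sample identifier; also keys the RNG stream, so
#'   cohorts are extensible without perturbing existing samples.
#' @param tmb_true overrides `cfg$tmb_true` for this sample.
#' @param with_normal simulate a matched normal?
#' @return list with `tumor` ([sample_callset()], assay `"exome"`),
#'   `normal` (callset or `NULL`), `tumor_coverage`, `normal_coverage`
#'   (profiles over the exome), and `truth` (one row per emitted tumor
#'   call: `key`, `truth_label`, `true_vaf`, `private`,
#'   `variant_class`).
#' @export
simulate_sample <- function(cfg, territories, sample_id,
                            tmb_true = cfg$tmb_true, with_normal = TRUE) {
  .with_seed(.derive_seed(cfg$seed, "sample", sample_id), {
    exome <- territories$exome
    depths_t <- .nb_depth(length(exome), cfg)
    tumor_cov <- .coverage_from_depths(exome, depths_t, sample_id, "exome")
    truth_tab <- .draw_patient_variants(cfg, territories, tmb_true)
    tum <- .realize_calls(truth_tab, depths_t, cfg)
    calls <- variant_calls(tum[, setdiff(names(tum),
                                         c("exon", "true_vaf", "private"))])
    tumor <- sample_callset(sample_id, "exome", calls, "tumor_only")
    truth <- tum[, c("chrom", "pos", "ref", "alt", "truth_label",
                     "true_vaf", "private", "variant_class")]
    truth$key <- call_key(truth)
    truth$sample_id <- sample_id
    normal <- NULL; normal_cov <- NULL
    if (with_normal) {
      normal_id <- paste0(sample_id, "_N")
      depths_n <- .nb_depth(length(exome), cfg)
      normal_cov <- .coverage_from_depths(exome, depths_n, normal_id,
                                          "exome")
      germ <- truth_tab[truth_tab$truth_label == "germline", , drop = FALSE]
      nor <- .realize_calls(germ, depths_n, cfg)
      ncalls <- variant_calls(nor[, setdiff(names(nor),
                                            c("exon", "true_vaf",
                                              "private"))])
      normal <- sample_callset(normal_id, "exome", ncalls, "tumor_only")
    }
    list(sample_id = sample_id, tumor = tumor, normal = normal,
         tumor_coverage = tumor_cov, normal_coverage = normal_cov,
         truth = truth)
  })
}

#' Project an exome sample onto a panel territory
#'
#' Keeps only the tumor calls inside the panel and re-realizes their read
#' support under an independent panel coverage draw, emulating a separate
#' sequencing assay of the same tumor. Variants whose panel re-draw
#' yields zero alt reads drop out, exactly as in a real assay.
#'
#' @param sim output of [simulate_sample()].
#' @param panel a panel territory `GRanges` from [simulate_territories()].
#' @param cfg the same [simulation_config()].
#' @return list with `callset` (tumor-only [sample_callset()] on the
#'   panel assay) and `coverage` (panel coverage profile).
#' @export
project_to_panel <- function(sim, panel, cfg) {
  assay <- territory_name(panel)
  .with_seed(.derive_seed(cfg$seed, "panel", sim$sample_id, assay), {
    depths_p <- .nb_depth(length(panel), cfg)
    cov <- .coverage_from_depths(panel, depths_p, sim$sample_id, assay)
    calls <- sim$tumor$calls
    keep <- in_territory(calls, panel)
    sub <- calls[keep, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(list(callset = sample_callset(sim$sample_id, assay,
                                           variant_calls(), "tumor_only"),
                  coverage = cov))
    truth <- sim$truth[match(call_key(sub), sim$truth$key), , drop = FALSE]
    # exon index within the panel for the depth lookup
    hit <- GenomicRanges::findOverlaps(.call_loci(sub), panel,
                                       select = "first")
    tab <- data.frame(sub[, c("chrom", "pos", "ref", "alt", "variant_class",
                              "splice_offset", "population_maf",
                              "in_dbsnp", "in_cosmic", "truth_label")],
                      exon = hit, true_vaf = truth$true_vaf,
                      stringsAsFactors = FALSE)
    out <- .realize_calls(tab, depths_p, cfg)
    ccalls <- variant_calls(out[, setdiff(names(out),
                                          c("exon", "true_vaf"))])
    list(callset = sample_callset(sim$sample_id, assay, ccalls,
                                  "tumor_only"),
         coverage = cov)
  })
}

#' Simulate a full multi-assay cohort
#'
#' @param cfg a [simulation_config()].
#' @param n_samples number of tumor samples.
#' @param tmb_true per-sample true TMB values (recycled).
#' @param paired logical vector (recycled): does the sample have a
#'   matched normal?
#' @param project_panels also project every sample onto every configured
#'   panel?
#' @return list of class `simulated_cohort` with `cfg`, `territories`,
#'   `pon`, `samples` (each: `sim` plus named `panels` list) and
#'   `truth` (row-bound truth table).
#' @export
simulate_cohort <- function(cfg, n_samples = 14L,
                            tmb_true = cfg$tmb_true, paired = TRUE,
                            project_panels = TRUE) {
  territories <- simulate_territories(cfg)
  pon <- simulate_pon(cfg, territories)
  tmb_true <- rep(tmb_true, length.out = n_samples)
  paired <- rep(paired, length.out = n_samples)
  samples <- lapply(seq_len(n_samples), function(i) {
    sid <- sprintf("sample_%02d", i)
    sim <- simulate_sample(cfg, territories, sid, tmb_true = tmb_true[i],
                           with_normal = paired[i])
    panels <- list()
    if (project_panels)
      panels <- lapply(territories$panels, function(p)
        project_to_panel(sim, p, cfg))
    list(sim = sim, panels = panels, tmb_true = tmb_true[i])
  })
  names(samples) <- vapply(samples, function(s) s$sim$sample_id, "")
  structure(list(cfg = cfg, territories = territories, pon = pon,
                 samples = samples,
                 truth = do.call(rbind, lapply(samples,
                                               function(s) s$sim$truth))),
            class = "simulated_cohort")
}
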