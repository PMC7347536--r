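# Small geometry for fast unit tests; acceptance tests use full scale.
small_cfg <- function(seed = 5, ...) {
  simulation_config(seed = seed, exome_mb = 3,
                    panel_specs = c(pA = 0.5, pB = 1.0),
                    germline_het_per_exome = 600L, ...)
}

test_that("simulated exome and panels hit their target sizes", {
  cfg <- simulation_config(seed = 2)
  terr <- simulate_territories(cfg)
  expect_gte(coding_mb(terr$exome), 35.5)
  expect_lte(coding_mb(terr$exome), 36.3)
  for (nm in names(cfg$panel_specs)) {
    expect_lte(abs(coding_mb(terr$panels[[nm]]) - cfg$panel_specs[[nm]]),
               0.01 * cfg$panel_specs[[nm]])
    # every panel interval is an exome interval
    hits <- GenomicRanges::countOverlaps(terr$panels[[nm]], terr$exome,
                                         type = "equal")
    expect_true(all(hits == 1))
  }
})

test_that("simulation is deterministic given the seed", {
  cfg <- small_cfg(seed = 42)
  t1 <- simulate_territories(cfg)
  t2 <- simulate_territories(cfg)
  expect_identical(GenomicRanges::start(t1$exome),
                   GenomicRanges::start(t2$exome))
  s1 <- simulate_sample(cfg, t1, "s1")
  s2 <- simulate_sample(cfg, t1, "s1")
  expect_identical(s1$tumor$calls, s2$tumor$calls)
  expect_identical(s1$normal$calls, s2$normal$calls)
  p1 <- simulate_pon(cfg, t1)
  p2 <- simulate_pon(cfg, t1)
  expect_identical(p1$entries, p2$entries)
  # per-sample streams: adding a sample does not perturb another
  other <- simulate_sample(cfg, t1, "s2")
  expect_identical(simulate_sample(cfg, t1, "s1")$tumor$calls,
                   s1$tumor$calls)
  expect_false(identical(other$tumor$calls, s1$tumor$calls))
})

test_that("somatic burden and VAF follow the configured model", {
  cfg <- small_cfg(seed = 8, tmb_true = 30, purity = 1.0,
                   artifact_rate_per_mb = 0)
  terr <- simulate_territories(cfg)
  sim <- simulate_sample(cfg, terr, "s1")
  som <- sim$truth[sim$truth$truth_label == "somatic", ]
  lambda <- 30 * coding_mb(terr$exome)
  expect_lt(abs(nrow(som) - lambda), 4 * sqrt(lambda))
  # heterozygous diploid expectation at purity 1
  expect_lt(abs(mean(som$true_vaf) - 0.5), 0.02)
  expect_equal(sum(sim$truth$truth_label == "artifact"), 0L)
})

test_that("artifacts are strand-skewed low-VAF C:G>T:A transitions", {
  cfg <- small_cfg(seed = 9, artifact_rate_per_mb = 30)
  terr <- simulate_territories(cfg)
  sim <- simulate_sample(cfg, terr, "s1")
  art_keys <- sim$truth$key[sim$truth$truth_label == "artifact"]
  art <- sim$tumor$calls[call_key(sim$tumor$calls) %in% art_keys, ]
  expect_gt(nrow(art), 30)
  expect_true(all(paste0(art$ref, ">", art$alt) %in% c("C>T", "G>A")))
  tr <- sim$truth[match(call_key(art), sim$truth$key), ]
  expect_true(all(tr$true_vaf >= 0.01 & tr$true_vaf <= 0.06))
  skew <- pmax(art$alt_fwd, art$alt_rev) / art$alt_depth
  expect_gt(mean(skew), 0.85)
})

test_that("truth labels map one-to-one onto emitted calls", {
  cfg <- small_cfg(seed = 10)
  terr <- simulate_territories(cfg)
  sim <- simulate_sample(cfg, terr, "s1")
  expect_setequal(call_key(sim$tumor$calls), sim$truth$key)
  expect_equal(anyDuplicated(sim$truth$key), 0L)
})

test_that("the panel of normals carries shared germline at high Af ratio risk", {
  cfg <- small_cfg(seed = 11)
  terr <- simulate_territories(cfg)
  pon <- simulate_pon(cfg, terr)
  expect_equal(pon$n_normals, cfg$n_normals_pon)
  sim <- simulate_sample(cfg, terr, "s1")
  known <- sim$truth[sim$truth$truth_label == "germline" &
                       !sim$truth$private, ]
  calls <- sim$tumor$calls
  kcalls <- calls[call_key(calls) %in% known$key, ]
  ratios <- pon_min_ratio(kcalls, pon)
  # nearly all shared germline variants are detected in some normal at a
  # comparable allelic fraction, so the ratio rule rejects them
  expect_gt(mean(is.finite(ratios)), 0.95)
  expect_gt(mean(ratios <= 4, na.rm = TRUE), 0.95)
  # somatic variants are absent from the panel and pass vacuously
  som <- calls[calls$truth_label %in% "somatic", ]
  expect_gt(mean(is.infinite(pon_min_ratio(som, pon))), 0.99)
})

test_that("panel projection keeps in-territory calls and re-draws depth", {
  cfg <- small_cfg(seed = 12, artifact_rate_per_mb = 0)
  terr <- simulate_territories(cfg)
  sim <- simulate_sample(cfg, terr, "s1")
  pp <- project_to_panel(sim, terr$panels$pB, cfg)
  expect_true(all(in_territory(pp$callset$calls, terr$panels$pB)))
  # identity projection: panel == exome keeps the variant keys
  full <- terr$exome
  S4Vectors::metadata(full)$territory_name <- "full"
  ppf <- project_to_panel(sim, full, cfg)
  expect_setequal(call_key(ppf$callset$calls), call_key(sim$tumor$calls))
  # depths are an independent draw
  expect_false(identical(ppf$callset$calls$total_depth,
                         sim$tumor$calls$total_depth))
  # retained somatic fraction tracks the territory ratio
  som_keys <- sim$truth$key[sim$truth$truth_label == "somatic"]
  frac <- mean(som_keys %in% call_key(pp$callset$calls))
  ratio <- coding_mb(terr$panels$pB) / coding_mb(terr$exome)
  expect_lt(abs(frac - ratio), 4 * sqrt(ratio * (1 - ratio) /
                                          length(som_keys)))
  # empty panel -> empty callset
  empty <- territory(name = "none")
  expect_equal(nrow(project_to_panel(sim, empty, cfg)$callset$calls), 0L)
})

test_that("germline overhead accounting is exact by construction", {
  cfg <- small_cfg(seed = 13)
  terr <- simulate_territories(cfg)
  pon <- simulate_pon(cfg, terr)
  sim <- simulate_sample(cfg, terr, "s1")
  fc <- filter_config(include_synonymous = TRUE)
  to <- run_tmb(sim$tumor, pon, sim$tumor_coverage, terr$exome, fc)
  paired_cs <- sample_callset(sim$sample_id, "exome", sim$tumor$calls,
                              "paired", matched_normal_id = "s1_N")
  pa <- run_tmb(paired_cs, pon, sim$tumor_coverage, terr$exome, fc,
                matched_normal = sim$normal)
  delta <- to$result$n_variants - pa$result$n_variants
  priv <- sim$truth$key[sim$truth$truth_label == "germline" &
                          sim$truth$private]
  survivors <- sum(to$verdicts$counted[to$verdicts$key %in% priv])
  expect_equal(delta, survivors)
})
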