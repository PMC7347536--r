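cfg0 <- filter_config()

test_that("class filter admits burden-relevant classes only", {
  expect_false(class_filter(make_call(variant_class = "synonymous"), cfg0))
  expect_true(class_filter(make_call(variant_class = "synonymous"),
                           filter_config(include_synonymous = TRUE)))
  expect_false(class_filter(make_call(variant_class = "other"), cfg0))
  for (cls in c("snv", "indel", "frameshift", "start_stop"))
    expect_true(class_filter(make_call(variant_class = cls), cfg0))
  expect_error(class_filter(make_call(variant_class = NA_character_)),
               "variant_class")
})

test_that("splice window is symmetric and inclusive at +/- 2 bp", {
  sp <- function(off) make_call(variant_class = "splice",
                                splice_offset = off)
  expect_true(splice_filter(sp(2L), cfg0))
  expect_true(splice_filter(sp(-2L), cfg0))
  expect_true(splice_filter(sp(0L), cfg0))
  expect_false(splice_filter(sp(3L), cfg0))
  expect_false(splice_filter(sp(-3L), cfg0))
  bad <- sp(1L); bad$splice_offset <- NA_integer_
  expect_error(splice_filter(bad, cfg0), "splice_offset")
  # non-splice classes pass vacuously
  expect_true(splice_filter(make_call(variant_class = "snv"), cfg0))
})

test_that("population MAF gate is strict at 0.01%", {
  expect_true(maf_filter(make_call(population_maf = 5e-5), cfg0))
  expect_false(maf_filter(make_call(population_maf = 2e-4), cfg0))
  expect_false(maf_filter(make_call(population_maf = 1e-4), cfg0))
  expect_true(maf_filter(make_call(), cfg0))  # unseen in resource
})

test_that("dbSNP members are removed unless in COSMIC", {
  expect_false(dbsnp_cosmic_filter(make_call(in_dbsnp = TRUE)))
  expect_true(dbsnp_cosmic_filter(make_call(in_dbsnp = TRUE,
                                            in_cosmic = TRUE)))
  expect_true(dbsnp_cosmic_filter(make_call()))
})

test_that("support thresholds are inclusive at their boundaries", {
  expect_true(support_filter(make_call(total_depth = 100L, alt_depth = 5L,
                                       mq_pass_fraction = 0.90), cfg0))
  expect_false(support_filter(make_call(total_depth = 100L, alt_depth = 4L),
                              cfg0))
  expect_false(support_filter(make_call(total_depth = 200L, alt_depth = 8L),
                              cfg0))  # vaf 0.04
  expect_false(support_filter(make_call(mq_pass_fraction = 0.89), cfg0))
})

test_that("panel-of-normals ratio filter is strict and vacuous on misses", {
  pon <- panel_of_normals(data.frame(chrom = "chr1", pos = 100L, ref = "C",
                                     alt = "T", normal_id = "n1",
                                     af = 0.05), n_normals = 21L)
  expect_true(pon_filter(make_call(alt_depth = 40L), pon, cfg0))   # 0.4/0.05 = 8
  expect_false(pon_filter(make_call(alt_depth = 10L), pon, cfg0))  # ratio 2
  expect_false(pon_filter(make_call(alt_depth = 20L), pon, cfg0))  # exactly 4
  expect_true(pon_filter(make_call(pos = 999L, alt_depth = 10L), pon, cfg0))
  expect_error(panel_of_normals(data.frame(chrom = "chr1", pos = 1L,
                                           ref = "A", alt = "T",
                                           normal_id = "n1", af = 0)),
               "allelic fractions")
  # the worst (largest) normal Af governs
  pon2 <- panel_of_normals(data.frame(chrom = "chr1", pos = 100L,
                                      ref = "C", alt = "T",
                                      normal_id = c("n1", "n2"),
                                      af = c(0.01, 0.2)))
  expect_false(pon_filter(make_call(alt_depth = 40L), pon2, cfg0))
})

test_that("cascade reports every failed rule independently", {
  germ <- make_call(pos = 1L, alt_depth = 50L, in_dbsnp = TRUE,
                    population_maf = 0.3)
  art <- make_call(pos = 2L, total_depth = 100L, alt_depth = 3L)
  clean <- make_call(pos = 3L, alt_depth = 40L)
  cs <- sample_callset("s", "a", rbind(germ, art, clean))
  v <- apply_cascade(cs, NULL, cfg0)
  v <- v[order(v$pos), ]
  expect_equal(v$failed_rules, c("maf;dbsnp", "support", ""))
  expect_equal(v$passed, c(FALSE, FALSE, TRUE))
  # verdict invariant: passed <=> no failed rules
  expect_equal(v$passed, v$failed_rules == "")
})

test_that("paired mode with an empty matched normal changes nothing", {
  cs <- random_callset(50, "s")
  pon <- random_pon(cs$calls)
  v1 <- apply_cascade(cs, pon, cfg0)
  paired <- sample_callset("s", "assay", cs$calls, "paired",
                           matched_normal_id = "s_N")
  empty_normal <- sample_callset("s_N", "assay", NULL)
  v2 <- apply_cascade(paired, pon, cfg0, matched_normal = empty_normal)
  expect_equal(v1$passed, v2$passed)
  expect_error(apply_cascade(paired, pon, cfg0), "matched normal")
})

test_that("cascade agrees with a straight-line oracle on random callsets", {
  set.seed(101)
  for (rep in 1:25) {
    cs <- random_callset(sample(1:120, 1))
    pon <- random_pon(cs$calls)
    cfg <- filter_config(include_synonymous = runif(1) < 0.5)
    v <- apply_cascade(cs, pon, cfg)
    o <- oracle_cascade(cs, pon, cfg)
    expect_equal(v$passed, unname(apply(o, 1, all)))
    for (rule in colnames(o))
      expect_equal(v[[rule]], unname(o[, rule]),
                   info = paste("rule", rule, "rep", rep))
  }
})

test_that("tightening any threshold never grows the pass set", {
  set.seed(202)
  cs <- random_callset(150)
  pon <- random_pon(cs$calls)
  base <- apply_cascade(cs, pon, cfg0)$passed
  tighter <- list(
    filter_config(min_vaf = 0.10), filter_config(min_alt_reads = 8L),
    filter_config(pon_ratio = 6), filter_config(maf_threshold = 1e-5),
    filter_config(splice_window_bp = 1L),
    filter_config(min_mq_pass_fraction = 0.95))
  for (cfg in tighter) {
    p <- apply_cascade(cs, pon, cfg)$passed
    expect_true(all(base | !p))  # p subset of base
  }
})

test_that("paired pass set is a subset of tumor-only; synonymous a superset", {
  set.seed(303)
  cs <- random_callset(150, "s")
  pon <- random_pon(cs$calls)
  to <- apply_cascade(cs, pon, cfg0)$passed
  normal <- random_callset(80, "s_N")
  paired <- sample_callset("s", "assay", cs$calls, "paired",
                           matched_normal_id = "s_N")
  pp <- apply_cascade(paired, pon, cfg0, matched_normal = normal)$passed
  expect_true(all(to | !pp))
  syn <- apply_cascade(cs, pon,
                       filter_config(include_synonymous = TRUE))$passed
  expect_true(all(syn | !to))
  gained <- cs$calls$variant_class[syn & !to]
  expect_true(all(gained == "synonymous"))
})
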