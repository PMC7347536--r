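test_that("variant call invariants are enforced", {
  expect_error(variant_calls(make_call(alt_depth = 120L)),
               "alt_depth exceeds")
  bad <- make_call(); bad$alt_fwd <- 1L; bad$alt_rev <- 1L
  expect_error(variant_calls(bad), "alt_fwd")
  bad <- make_call(); bad$vaf <- 0.9
  expect_error(variant_calls(bad), "vaf inconsistent")
  expect_error(variant_calls(make_call(variant_class = "weird")),
               "unknown variant_class")
  expect_error(variant_calls(make_call(population_maf = 1.5)),
               "population_maf")
  expect_error(variant_calls(rbind(make_call(), make_call())),
               "duplicate")
  # a valid set comes back sorted by (chrom, pos)
  cs <- variant_calls(rbind(make_call(chrom = "chr2", pos = 5L),
                            make_call(chrom = "chr1", pos = 9L)))
  expect_equal(cs$chrom, c("chr1", "chr2"))
})

test_that("read_vcf splits multi-allelic records and computes VAF", {
  path <- write_vcf_fixture(c(vcf_header_fixture,
    "chr1\t100\t.\tA\tT\t.\tPASS\tDP=100;AD=95,5;SAF=3;SAR=2;MQPF=0.98;CLASS=snv",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\tDP=80;AD=60,15,5;SAF=8,3;SAR=7,2;MQPF=0.95;CLASS=snv,synonymous;PMAF=0.001,.;DB",
    "chr1\t300\t.\tG\tA\t.\tPASS\tDP=50;AD=25,25;MQPF=1;CLASS=splice;SPLOFF=-2;COSMIC"))
  cs <- read_vcf(path, sample_id = "s1")
  expect_s3_class(cs, "sample_callset")
  expect_equal(nrow(cs$calls), 4L)          # 1 + 2 + 1 alt alleles
  c100 <- cs$calls[cs$calls$pos == 100L, ]
  expect_equal(c100$vaf, 0.05)
  expect_equal(c100$alt_fwd, 3L)
  # split record conserves alt depth and distributes per-allele tags
  c200 <- cs$calls[cs$calls$pos == 200L, ]
  expect_equal(sum(c200$alt_depth), 20L)
  expect_equal(c200$variant_class[order(c200$alt)], c("synonymous", "snv"))
  expect_equal(c200$in_dbsnp, c(TRUE, TRUE))
  expect_equal(c200$population_maf[c200$alt == "T"], 0.001)
  expect_true(is.na(c200$population_maf[c200$alt == "G"]))
  c300 <- cs$calls[cs$calls$pos == 300L, ]
  expect_equal(c300$splice_offset, -2L)
  expect_true(c300$in_cosmic)
  expect_false(c300$in_dbsnp)
  # missing optional tags stay absent, never defaulted
  expect_true(is.na(c300$population_maf))
})

test_that("read_vcf handles empty bodies and missing required tags", {
  cs <- read_vcf(write_vcf_fixture(vcf_header_fixture))
  expect_equal(nrow(cs$calls), 0L)
  hdr_no_ad <- vcf_header_fixture[!grepl("ID=AD", vcf_header_fixture)]
  expect_error(read_vcf(write_vcf_fixture(c(hdr_no_ad,
    "chr1\t1\t.\tA\tT\t.\t.\tDP=10"))), "required INFO tag")
})

test_that("filtered VCF round-trips calls and verdicts", {
  cs <- random_callset(40, "rt")
  pon <- random_pon(cs$calls)
  verdicts <- apply_cascade(cs, pon, filter_config())
  path <- tempfile(fileext = ".vcf")
  write_filtered_vcf(cs, verdicts, path)
  back <- read_vcf(path, sample_id = "rt", assay_id = "assay")
  expect_equal(call_key(back$calls), call_key(cs$calls))
  expect_equal(back$calls$total_depth, cs$calls$total_depth)
  expect_equal(back$calls$alt_depth, cs$calls$alt_depth)
  expect_equal(back$calls$vaf, cs$calls$vaf, tolerance = 1e-6)
  expect_equal(back$calls$variant_class, cs$calls$variant_class)
  expect_equal(back$calls$in_dbsnp, cs$calls$in_dbsnp)
  filt <- attr(back$calls, "filter")
  expect_equal(filt == "PASS", verdicts$passed)
  # failed calls carry all their rule codes, semicolon-separated
  i <- which(!verdicts$passed)
  if (length(i))
    expect_equal(filt[i], verdicts$failed_rules[i])
  expect_error(write_filtered_vcf(cs, verdicts[-1, ], tempfile()),
               "verdicts missing")
})

test_that("read_bed merges abutting intervals and validates bounds", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t100\t200"), path)
  t <- read_bed(path)
  expect_equal(length(t), 1L)
  expect_equal(coding_mb(t), 2e-4)
  writeLines(c("chr1\t0\t100", "chr1\t500\t400"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(character(), path)
  expect_equal(coding_mb(read_bed(path)), 0)
})

test_that("territory size matches panel coding megabases", {
  # 1.2 MB of intervals -> 1.2 coding MB
  t <- territory("chr1", seq(0, by = 2000, length.out = 600),
                 seq(1000, by = 2000, length.out = 600) + 1000)
  expect_equal(coding_mb(t), 1.2)
})

test_that("territory merge is idempotent and order-independent", {
  set.seed(11)
  s <- sample.int(1e5, 30)
  e <- s + sample.int(500, 30)
  t1 <- territory(rep("chr1", 30), s, e)
  perm <- sample.int(30)
  t2 <- territory(rep("chr1", 30), s[perm], e[perm])
  expect_identical(GenomicRanges::start(t1), GenomicRanges::start(t2))
  t3 <- territory(as.character(GenomicRanges::seqnames(t1)),
                  GenomicRanges::start(t1) - 1L, GenomicRanges::end(t1))
  expect_identical(GenomicRanges::start(t1), GenomicRanges::start(t3))
})

test_that("coverage profiles clip, zero-fill and reject bad input", {
  terr <- territory("chr1", 0L, 1000L)
  cov <- coverage_profile("chr1", 0L, 500L, 20L, terr)
  expect_equal(depth_at(cov, "chr1", 10L), 20)
  # second half of the territory is explicit depth 0, not undefined
  expect_equal(depth_at(cov, "chr1", 800L), 0)
  # outside the territory queries are rejected
  expect_error(depth_at(cov, "chr1", 5000L), "outside")
  # interval overlapping the edge is clipped
  cov2 <- coverage_profile("chr1", 900L, 5000L, 30L, terr)
  expect_equal(depth_at(cov2, "chr1", 950L), 30)
  expect_equal(sum(GenomicRanges::width(cov2)), 1000L)
  path <- tempfile(fileext = ".tsv")
  writeLines("chr1\t0\t100\t-3", path)
  expect_error(read_coverage(path, terr), "negative depth")
})

test_that("coverage TSVs round-trip", {
  terr <- territory(c("chr1", "chr2"), c(0L, 0L), c(400L, 300L))
  cov <- coverage_profile(c("chr1", "chr2"), c(0L, 0L), c(400L, 300L),
                          c(25L, 8L), terr, "s")
  path <- tempfile(fileext = ".tsv")
  write_coverage(cov, path)
  back <- read_coverage(path, terr, "s")
  expect_equal(depth_at(back, c("chr1", "chr2"), c(100L, 100L)), c(25, 8))
})
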