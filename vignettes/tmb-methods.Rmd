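---
title: "Measuring and harmonizing tumor mutational burden with tmbpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and harmonizing tumor mutational burden with tmbpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbpanel)
```

## Scope and model

Tumor mutational burden (TMB) is estimated here as

$$\mathrm{TMB} = \frac{\#\{\text{variants passing the filter cascade at callable loci}\}}{\text{callable megabases}}$$

on a fixed coding territory (a gene panel's coding subset or the exome's
overlap with annotated coding sequence). The package starts from *called,
annotated* variants — VCFs carrying depth, strand counts, functional
class, population allele frequency and database membership as INFO tags —
and deliberately contains no read-level processing: alignment, UMI
consensus building and variant calling are upstream concerns, and their
vendor-specific behavior is exactly what the harmonization statistics are
meant to compare across assays.

### The filter cascade

Six rules decide whether a call counts toward the burden. They are
evaluated *independently* (no short-circuiting) so every verdict records
all reasons for failure; the final pass set is identical to a sequential
pipeline.

| rule | condition to pass | default |
|---|---|---|
| class | SNV, indel, frameshift, start/stop, splice (synonymous only in syn-inclusive mode; `other` never) | — |
| splice | \|offset to exon/intron boundary\| ≤ window | 2 bp |
| maf | population MAF strictly below threshold, or unseen | 1e-4 (0.01%) |
| dbsnp | not (in dbSNP and absent from COSMIC) | — |
| support | alt reads ≥ minimum and VAF ≥ cutoff (inclusive) | 5 reads, 5% |
| mq | fraction of reads with mapping quality > 1 ≥ minimum | 90% |
| pon | Af_tumor/Af_normal strictly > ratio for *every* normal carrying the variant | 4 |

Boundary semantics follow the wording of the thresholds: "or more" and
"at least" make the support bounds inclusive, while the MAF gate and the
panel-of-normals ratio are strict inequalities. The minimum-read
threshold is applied to alt-supporting reads: a total-depth reading of
"5 reads" would be incoherent with a simultaneous 5% VAF requirement
(0.25 alt reads). The panel-of-normals condition is universal over the
normals in which the variant was *detected*; normals without the variant
satisfy it vacuously — the alternative reading would fail every variant
absent from all normals. A variant unseen in the population resource has
an *absent* MAF and passes the frequency gate; absence of evidence is not
a frequency of zero.

Paired calling is implemented as a special case of the panel-of-normals
rule: the matched normal's allelic fractions are merged into the panel
before filtering, so the patient's own germline (ratio ≈ 1 at
heterozygous sites) is removed. Consequently the paired pass set is
always a subset of the tumor-only pass set, and the difference between
the two — the *germline overhead* — is an operational estimate of
residual germline contamination in tumor-only TMB.

### The denominator

A base is callable iff its depth strictly exceeds `min_coverage`
(default 15; a base needs ≥ 16×). The numerator is restricted to calls at
callable loci inside the territory, so numerator and denominator live in
the same coverage-conditioned universe; the source text is silent on
this, and counting uncallable loci in the numerator would make TMB
inconsistent under territory subsetting. A sample with zero callable
megabases gets an `NA` burden plus a warning — undersequencing produces
an undefined estimate, not a zero one.

### Harmonization statistics

Panel TMB values are compared against a reference exome (paired when
available, tumor-only otherwise; the reference series is always the
exome's non-synonymous burden). For each panel and synonymous setting the
report contains:

* Pearson r, converted to $t = r\sqrt{(n-2)/(1-r^2)}$ with a two-sided
  p-value on $n-2$ df and Bonferroni correction across all rows of the
  report (the family is the set of panel/setting combinations tested in
  one run). Sidedness is not dictated by the source material; two-sided
  is the conservative default.
* the conversion factor mean(reference)/mean(panel), which equalizes the
  two cohort means exactly. Following the original procedure the factor
  is estimated and applied on the same cohort; this is circular by
  construction and is reported as such rather than "fixed" with a
  fit/apply split.
* OPA/PPA/NPA of the TMB-high classification at a cutoff of 10 v/mb
  after factor correction. The positive class is *strictly* above the
  cutoff; a corrected value of exactly 10 is negative. Percentages with
  empty denominators (e.g. PPA in an all-low cohort) are `NA`, not 0 or
  100.

### Artifact diagnostics

FFPE fixation deaminates cytosine, producing C:G>T:A calls at low VAF
with strand imbalance. Two diagnostics are provided and kept *out* of the
filter cascade by default (they inform review, they do not silently
change the burden):

* the transition ratio — the fraction of passing variants that are C>T
  on either strand (pyrimidine-collapsed), with the denominator including
  indels ("all passing variants"); an SNV-only denominator is a switch.
* a strand-imbalance flag: a two-sided exact binomial test of the
  forward/reverse alt-read split against 0.5 at α = 0.01. This is a
  deliberately simple stand-in for caller-specific orientation models,
  whose exact statistics are not public; the exact test guarantees
  a false-positive rate ≤ α by construction and is property-tested for
  it.

The VAF-stratified report re-runs the cascade at several VAF cutoffs
(default 2% and 5%) and reports pass counts, transition ratios and flag
fractions — the sensitivity analysis for lowering the support cutoff into
the artifact-rich low-VAF range.

## The synthetic cohort generator

No patient data accompany the analysis this package implements, so the
generator is a first-class module: it emulates the *statistical
structure* the pipeline consumes, with full truth labels.

* **Territories.** Exon-like intervals with log-normal lengths (median
  150 bp, log-sd 0.6) chained over 22 chromosomes to a 35.9 MB exome;
  panels are random subsets of whole exome intervals hitting their coding
  size (defaults 1.2, 1.24, 1.2, 1.1 and 1.3 MB) to within 1%.
* **Coverage.** Per-exon negative-binomial depth, mean 120× and size 8 —
  heavy enough tails to exercise the callable-territory logic without
  making low coverage the dominant error source. Each assay re-draws
  depth independently, emulating separate sequencing of the same tumor.
* **Somatic variants.** Poisson-placed uniformly over the exome at
  `tmb_true` per MB; VAF ~ Beta centered on purity/2 (concentration 20) —
  a single-clone diploid model, the minimal structure supporting the VAF
  cutoff experiments. Substitution spectrum with a 40% C:G>T:A share, so
  passing-set transition ratios land in the 0.35–0.5 range typical of
  FFPE cohorts; 25% synonymous.
* **Germline variants.** A shared population pool (each individual
  carries a site with probability 0.5) plus private variants. Defaults:
  6700 coding variants per individual, 3% private. With these, tumor-only
  exome calling carries ≈ 200 germline survivors (≈ 150 non-synonymous)
  ≈ 4–6 v/mb of overhead — the regime reported for real tumor-only exomes.
  This is a calibration anchor, not a reproduction claim: the pool is far
  smaller than a real population resource, and linkage, ethnicity
  structure and frequency-dependent carrier probabilities are absent.
* **Artifacts.** 0.5 per MB, all C:G>T:A, VAF ~ U(0.01, 0.06), 95% of
  alt reads on one strand, tumor-only. Roughly a fifth exceed the 5% VAF
  cutoff, leaving ≈ 0.1 v/mb of pass-through — visible, but inside the
  tolerance of burden recovery; diagnostics tests raise the rate
  explicitly when they need a strong signal.
* **Panel of normals.** 21 exome normals drawing from the same germline
  pool with re-sampled allelic fractions, plus ~30 random low-AF noise
  sites per normal.

Randomness is organized as one derived stream per (seed, purpose,
sample), so adding samples to a cohort never perturbs existing ones, and
identical configurations yield byte-identical cohort directories.

What passing tests on this generator do **not** show: robustness to
multi-allelic artifact clusters, subclonal architecture, CNV-driven VAF
distortion, microsatellite instability, or mis-annotation of variant
class — none of which the generator emulates.

## Numerical and design choices

* Coordinates are 1-based internally (VCF convention); BED and coverage
  TSV inputs are 0-based half-open and converted at the I/O boundary
  only. Multi-allelic records are split into per-alt calls before any
  filtering, conserving alt depths.
* The cascade's verdict table keeps the support rule split into `support`
  (reads + VAF) and `mq` codes so audits can distinguish the two.
* Territory merging uses interval reduction (overlapping *and* abutting
  intervals merge); merging is idempotent and order-independent.
* `pearson_with_p` refuses zero-variance input (a degenerate-input error
  is more useful than `r = NaN`) and returns `p = 0` at |r| = 1, where
  the t transform diverges.
* Problem sizes in the test suite were chosen to make the statistical
  assertions sharp at fixed seeds: 1000 random callsets for cascade/oracle
  equivalence, 20 samples per burden stratum (2–40 v/mb) for parameter
  recovery, 10 replicate cohorts of 20 samples for the panel-size
  variance decay check, and 10,000 balanced draws for the strand-flag
  error rate.
* The acceptance script uses a 14-sample cohort with 7 matched normals —
  the same shape as the study it mirrors — and a reduced 40-sample
  recovery grid.

## Known limitations

* Annotation (variant class, MAF, database flags) is consumed, never
  computed; a mis-annotated input propagates.
* The strand-imbalance flag is a generic exact test, not a read
  orientation model; it has no power below ~8 alt reads at α = 0.01.
* Conversion factors are cohort-mean ratios; no regression-based
  (Deming/orthogonal) calibration is provided.
* The generator's germline realism is limited to what the germline gates
  consume (membership flags, MAF, panel-of-normals allelic fractions).
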