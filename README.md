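# tmbpanel

Tumor mutational burden (TMB) estimation from annotated variant calls, and
harmonization of TMB across targeted gene panels and whole-exome
sequencing (WES).

TMB — somatic variants per megabase of interrogated coding territory — is
a predictive biomarker for immune-checkpoint therapy. Measuring it on a
1–1.3 MB gene panel instead of a 36 MB exome is attractive in routine
diagnostics, but panel values must be placed on the exome scale, residual
germline variants inflate tumor-only calling, and FFPE deamination
artifacts (C:G>T:A, low VAF, strand-skewed) distort the numerator. This
package implements, as reusable and tested R functions, the full
measurement procedure and the cross-assay comparison statistics, plus a
deterministic synthetic cohort generator with somatic/germline/artifact
truth labels so that every stage can be validated without patient data.

It is intended for bioinformaticians validating or comparing TMB assays,
and for method developers who need a transparent reference implementation
of the filter cascade and harmonization statistics.

## The method

**Filter cascade.** A called variant enters the TMB numerator iff it
passes all of:

* class gate: SNVs, indels, frameshifts, start/stop and splice-altering
  variants count; coding synonymous variants only in the syn-inclusive
  mode; splice variants must lie within ±2 bp of the exon/intron boundary;
* germline resource gate: population MAF < 0.01% (strict), and dbSNP
  members are removed unless present in COSMIC;
* support gate: ≥ 5 alt reads, allelic fraction (Af, VAF) ≥ 5%, and ≥ 90%
  of reads with mapping quality > 1;
* panel-of-normals gate: for every normal in which the variant was
  detected, Af_tumor / Af_normal > 4 (strict); in paired mode the matched
  normal is merged into the panel of normals first, which removes the
  patient's own germline directly.

**Burden.** TMB = (passing variants at callable loci) / (callable MB),
where a base is callable iff its depth strictly exceeds 15. A sample with
no callable territory has an undefined (NA) burden, never zero.

**Harmonization.** For each panel against the reference exome: Pearson r
with p-value from t = r·sqrt((n−2)/(1−r²)) on n−2 df, Bonferroni-corrected
across the report; conversion factor = mean(exome TMB)/mean(panel TMB);
overall/positive/negative percent agreement (OPA/PPA/NPA) of the TMB-high
classification (> 10 v/mb, strict) after factor correction; germline
overhead = tumor-only minus paired pass counts; and FFPE diagnostics
(C:G>T:A transition ratio overall and per VAF bin, exact-binomial strand
imbalance flags).

## Worked example

```r
library(tmbpanel)

cfg <- simulation_config(seed = 7, exome_mb = 3,
                         panel_specs = c(p1 = 0.5, p2 = 1.0),
                         germline_het_per_exome = 600L)
terr <- simulate_territories(cfg)
pon  <- simulate_pon(cfg, terr)
sim  <- simulate_sample(cfg, terr, "s1", tmb_true = 10)

# tumor-only analysis
to <- run_tmb(sim$tumor, pon, sim$tumor_coverage, terr$exome,
              filter_config(include_synonymous = TRUE))
to$result
#>   sample_id assay_id       mode include_synonymous n_variants callable_mb
#> 1        s1    exome tumor_only               TRUE         42    3.000038
#>        tmb min_coverage
#> 1 13.99982           15

# paired analysis of the same callset
paired <- sample_callset("s1", "exome", sim$tumor$calls, "paired",
                         matched_normal_id = "s1_N")
pa <- run_tmb(paired, pon, sim$tumor_coverage, terr$exome,
              filter_config(include_synonymous = TRUE),
              matched_normal = sim$normal)
pa$result$tmb
#> [1] 9.333215
```

The tumor-only burden (14.0 v/mb) exceeds the paired burden (9.3 v/mb,
close to the simulated truth of 10): the difference is the germline
overhead — exactly the 14 private germline variants that survive
tumor-only filtering, as `germline_overhead(to$result, pa$result)`
confirms.

Cohort-level workflow (also available as subcommands of the
`inst/scripts/tmbpanel` Rscript):

```r
cohort <- simulate_cohort(simulation_config(seed = 1), n_samples = 14,
                          tmb_true = draw_cohort_tmb(simulation_config(seed = 1), 14),
                          paired = rep(c(TRUE, FALSE), each = 7))
called <- call_cohort(cohort)               # per sample x assay x mode TMB
compare_cohort(called)                      # r, t, p, factor, OPA/PPA/NPA
overhead_cohort(called)                     # germline overhead per sample
```

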