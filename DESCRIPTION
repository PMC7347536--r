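Package: tmbpanel
Title: Tumor Mutational Burden Estimation and Cross-Panel Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes tumor mutational burden (TMB) from annotated somatic
    variant call sets using a reproducible filter cascade (variant-class and
    splice-window gates, population allele-frequency and dbSNP/COSMIC
    germline subtraction, read-support and mapping-quality thresholds, and a
    panel-of-normals allelic-fraction ratio filter) together with a
    coverage-conditioned callable-megabase denominator. Provides cross-assay
    harmonization statistics for comparing targeted gene panels against
    whole-exome sequencing (Pearson correlation with t-statistic p-values
    and Bonferroni correction, exome/panel conversion factors, overall,
    positive and negative percent agreement at a variants-per-megabase
    cutoff), quantification of residual germline overhead in tumor-only
    calling, and FFPE deamination-artifact diagnostics (C:G>T:A transition
    ratios and strand-imbalance flags). Includes a fully deterministic
    synthetic cohort generator with somatic, germline and artifact truth
    labels so every pipeline stage can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
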