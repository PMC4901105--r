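Package: t2dgrs
Title: Population-Based Evaluation of Type 2 Diabetes Risk Variants and
    Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic-epidemiology pipeline for population-based evaluation
    of established type 2 diabetes risk variants: genotype and sample
    quality control (call rate, Hardy-Weinberg, heterozygosity F),
    covariate-adjusted per-SNP logistic association, inverse-variance
    fixed-effect meta-analysis with Cochran's Q heterogeneity, winner's
    curse and spectrum-bias quantification by weighted regression through
    the origin, weighted genetic risk scores (overall, beta-cell,
    insulin-resistance) with rescaling and centre-mean imputation, ROC
    discrimination with DeLong comparisons and cross-validated weights,
    and gene-adiposity interaction analysis.  A synthetic cohort
    generator with known ground truth makes every stage testable without
    access-controlled individual-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    jsonlite
Config/testthat/edition: 3
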