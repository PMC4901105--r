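---
title: "Methods: population-based evaluation of type 2 diabetes risk variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-based evaluation of type 2 diabetes risk variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dgrs)
```

# The problem

Most effect-size estimates for type 2 diabetes risk variants come from
case-control discovery studies.  Two mechanisms inflate them relative to
what a general population experiences: *winner's curse* (a variant is only
reported once its estimate crosses a stringent significance threshold, so
the reported estimate is conditionally biased upward, especially when power
is limited) and *spectrum bias* (cases drawn from the clinical extreme and
"hyper-normal" controls exaggerate the genotype-phenotype contrast).
Population-based cohorts give estimates free of both.  This package
implements the full analysis chain used for such an evaluation --
genotype/sample QC, covariate-adjusted per-SNP association, fixed-effect
meta-analysis against external consortium results, attenuation
quantification, weighted genetic risk scores (GRS), ROC discrimination and
gene-adiposity interaction -- together with a synthetic cohort generator
with known ground truth, so that every stage is testable without
access-controlled individual-level data.

# Models and procedures

## Per-SNP association

Disease status is regressed on the 0/1/2 risk-allele dosage by maximum
likelihood logistic regression, adjusted for age, sex and regional centre
(centre enters as indicator terms).  Wald 95% intervals use z = 1.959964
throughout the package; the exact quantile rather than 1.96 matters when
pooled odds ratios are compared with printed tables at a tolerance of
±0.01.  Separation and non-convergence are flagged rather than silently
returned; no penalised fallback is applied by default, matching common
practice even for variants with minor allele frequencies of a few per
mille.

## Meta-analysis

External results are consumed as printed OR (95% CI) triples;
`se_from_ci()` recovers the log-OR and its SE as
`(ln hi - ln lo) / (2 * 1.959964)`.  Pooling is inverse-variance
fixed-effects; Cochran's Q on k - 1 df assesses heterogeneity, with a
Bonferroni threshold of 0.05/(55 x 3) = 3.0e-4 when a ~55-SNP panel is
tested under three study comparisons.  Because the inputs are rounded to
two decimals, recovered SEs carry rounding error; pooled ORs are reproducible
to about ±0.01 and heterogeneity p-values to roughly one part in ten, which
is the tolerance the tests use.

## Attenuation (winner's curse / spectrum bias)

The headline statistic is the slope of a weighted least-squares regression
through the origin of population log-ORs on reference (discovery) log-ORs,
weights 1/se² of the population estimate only.  The proportional reduction
is 1 - slope with a Wald interval and a test against unity.  Using only the
target-side variance matches the stated inverse-variance weighting; a
bivariate errors-in-variables treatment is deliberately out of scope.  The
published per-SNP external estimates behind the original 19%/22%/15%
figures live in supplementary tables that are not bundled, so those exact
numbers are treated as context; the acceptance surface is simulation-based
recovery (a known multiplicative attenuation of 0.80 is recovered as a
20% reduction on average).

## Genetic risk scores

Weighted scores use natural-log per-allele ORs as weights and are rescaled
by `total risk alleles / (2 x sum of weights)`, with "total risk alleles"
read as 2M for an M-SNP score (the maximal allele count).  This reading
makes the identity exact: with equal weights the rescaled score *is* the
risk-allele count, and one rescaled point corresponds on average to one
additional risk allele.  Missing genotypes are imputed with the mean
observed dosage of the SNP within the individual's regional centre (overall
mean as fallback).  Mechanism classification (beta-cell dysfunction vs
insulin resistance) follows an evidence-flag hierarchy: any beta-cell
criterion wins; IR requires an IR criterion and no primarily
obesity-mediated action.  The obesity criterion is implemented as an
exclusion (not an annotation); the published wording is ambiguous and the
tie-break (BC over IR) is this package's configurable choice.  The
published 25-SNP/7-SNP score memberships are supplementary-material
content and therefore configuration input, not package constants.

Quartile associations use sample quartiles with boundary ties assigned to
the lower quartile, and report floating absolute risks: every level,
including the reference, receives a floated variance such that any pairwise
contrast variance is approximated by the sum of the two floats.  Floats are
fitted by least squares on all pairwise contrast variances weighted by
inverse squared contrast variance, solved with the minimum-norm
pseudoinverse (exact for two levels; within 5% for the 4-level cases the
tests exercise).

## Discrimination

The C-statistic is computed by the midrank (placement) formula, ties
counting one half, with the DeLong structural-components variance; paired
score comparisons use the DeLong covariance of placements.  Cross-validated
weights emulate leave-0.1%-out validation: folds come from a seeded
permutation, per-SNP cohort estimates are refitted excluding each fold,
combined with external estimates by fixed-effect meta-analysis, and applied
only to held-out individuals.  The fold count is a parameter (k = 1000
reproduces 0.1% folds at the emulated cohort size; tests run k = 5-20).
Whether a baseline covariate model should accompany the GRS in the ROC is
left to the caller: scores are passed as-is, so either variant can be
assessed.

## Stratification and interaction

BMI strata follow the WHO Asian cut-points (normal < 23, overweight
23-27.5, obese >= 27.5 kg/m²; boundary values belong to the upper class as
the class definitions state).  Other adiposity measures use sex-specific
tertiles computed on the analysis sample, boundary ties to the lower
tertile.  Interaction is tested primarily with the continuous adiposity
variable in a single model (GRS + variable + product term, adjusted for
age, sex, centre) and secondarily with ordinal stratum coding; the original
computation basis is unstated, so both are available and neither is
asserted as "the" original.  The suite also verifies the collider caveat:
when the score lowers adiposity while both raise disease risk, stratifying
on adiposity manufactures apparent between-stratum heterogeneity with no
true interaction in the generator.

## Multiple testing and inflation

Holm step-down (FWER), Benjamini-Hochberg step-up (FDR) and a
permutation max-|z| procedure are provided.  The permutation statistic is a
score test of each dosage against the null covariate model, so one null fit
serves all SNPs per permutation; the adjusted p is
`(1 + #{perm max >= obs}) / (n_perm + 1)`.  The genomic inflation factor is
the median association chi-square over 0.4549364, rescaled to a
1,000-case/1,000-control equivalent with raw case/control counts (whether
effective counts were used originally is unstated; raw counts are used and
recorded).

## Directional concordance

The sign test is the exact binomial tail P(X >= k | n, 1/2).  The
one-sided tail is reported: the published concordance p-values
(2.3e-8 for 48/56, 9.73e-9 for 37/40) equal the one-sided tail even though
the surrounding text describes p-values globally as two-sided; the package
matches the printed numbers and documents the discrepancy here.

# The synthetic cohort generator

The generator emulates the study conditions of a large Chinese
population-based biobank: ten regional centres; 7.6% diabetes prevalence;
40.5% men; age 51.4 (SD 10.7) years truncated to 30-79; sex-specific
adiposity distributions (BMI 23.4/23.8 (3.2/3.5) kg/m², WC 82.0/79.1
(9.7/9.6) cm, WHR 0.90/0.87 (0.06/0.07), PBF 21.9/32.1 (6.2/7.2)% for
men/women) drawn jointly with a fixed correlation structure (BMI-WC 0.80,
BMI-PBF 0.75, WC-WHR 0.70, WC-PBF 0.70, BMI-WHR 0.45, WHR-PBF 0.45 --
realistic round values, chosen once).  The default SNP panel is the 52
GRS-eligible variants with their observed risk-allele frequencies and true
per-allele log-ORs set to the published population-based estimates (ORs
roughly 0.88-1.92, bulk 1.0-1.3).

Disease follows a logistic model whose intercept is solved by bisection so
the expected prevalence over the simulated covariates matches the target to
1e-4.  Status is generated through an explicit latent liability
(intercept + linear predictor + standard logistic noise); severity for
spectrum-bias sampling *is* that liability, a deliberate, testable stand-in
-- the original recruitment's glucose-screening design is not described
quantitatively and no claim is made about it.  Covariate effects default to
log-OR 0.05 per year of age, 0.10 for women, 0.10 per kg/m² BMI and
centre effects N(0, 0.15) -- round values giving age and adiposity
gradients of realistic size.  The optional gene-adiposity interaction adds
`interaction_coef` per unit of centred BMI to every SNP's log-OR.

Genotypes are independent across SNPs under Hardy-Weinberg proportions; no
linkage disequilibrium, population structure or relatedness is simulated
(all deliberately out of scope).  Per-SNP missingness defaults to 0.2%,
the near-complete call-rate regime of an array panel after SNP-level QC;
this keeps the 98% sample call-rate filter removing well under 1% of
samples, as seen in practice.  Consequences for interpretation: passing
tests show the estimators are calibrated and the pipeline is correct under
independence and clean missingness; they say nothing about LD-induced
redundancy between score SNPs, differential missingness, or relatedness.

A note on estimands: with many SNPs in one cohort, a marginal one-SNP
logistic fit targets a non-collapsible, slightly attenuated version of the
generating conditional log-OR.  Calibration (bias, CI coverage) is
therefore assessed against the joint logistic refit, whose coefficients are
the generator's parameters; marginal fits are exercised everywhere else.

# Numerical choices and degenerate inputs

* z = 1.959964 for all 95% intervals, construction and recovery alike, so
  CI round-trips are exact.
* Monomorphic SNPs: HWE chi-square 0, p 1, flagged (not an error) and
  dropped before association.
* A fasting time of exactly 8 h satisfies neither random-glucose screening
  rule by default (the rules are strict inequalities); configurable.
* The heterozygosity F "SD score" is a robust z (median, MAD x 1.4826);
  the original normalisation is unspecified, this choice is recorded, not
  asserted.
* Quartile/tertile boundary ties go to the lower group; BMI class
  boundaries go to the upper class (the class definitions are half-open in
  that direction).
* Strand-ambiguous (A/T, C/G) SNPs are warned about and never
  strand-flipped.
* Sex-mismatch checks are accepted as input flags; no intensity data is in
  scope.

# Problem sizes used by the test-suite and scripts

The bundled analyses and tests run at reduced but adequate sizes, chosen as
the package's own trade-off between Monte-Carlo error and desk runtime:
simulated cohorts of 1,500-50,000 individuals (analysis scripts use
20,000 x 52 SNPs), 200 replicates for bias/coverage and attenuation
recovery, 2,000 replicates for size calibration of the association,
interaction and permutation procedures, and 10-40 replicates for
discrimination and winner's-curse demonstrations.  The generator's default
cohort size remains the emulated 93,131.

# Known limitations

* No LD, haplotypes, population structure or relatedness in the generator;
  no mixed-model association.
* No random-effects meta-analysis (the pooling of interest is
  fixed-effects) and no analytic winner's-curse correction (the pipeline
  measures attenuation, it does not deconvolve it).
* The published per-SNP external weights and the exact beta-cell/IR score
  memberships are supplementary-material inputs, not package constants;
  analyses here use the bundled published cohort estimates or synthetic
  truth instead.
* VCF input reads the GT field only.
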