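# t2dgrs

Population-based evaluation of established type 2 diabetes risk variants,
as a tested R package plus a set of numbered analysis scripts.  It is aimed
at genetic epidemiologists who need population-level (rather than
case-control discovery) effect sizes: per-SNP covariate-adjusted logistic
association, inverse-variance fixed-effect meta-analysis with Cochran's Q,
quantification of winner's-curse / spectrum-bias attenuation, weighted
genetic risk scores with rescaling and centre-mean imputation, ROC
discrimination with DeLong comparisons, and gene–adiposity interaction
analysis.  A synthetic cohort generator with known ground truth (52-SNP
panel at published risk-allele frequencies, ten regional centres, 7.6%
diabetes prevalence, realistic adiposity distributions) makes every stage
testable without access-controlled individual-level data.

## The statistics at the core

* **Association:** per-allele log-OR `β` from logistic regression of
  case status on risk-allele dosage g ∈ {0,1,2}, adjusted for age, sex and
  regional centre; Wald CI with z = 1.959964.
* **Meta-analysis:** study SEs recovered from printed CIs as
  `se = (ln hi − ln lo)/(2·1.959964)`; fixed-effect pooling
  `β̂ = Σwβ/Σw`, `w = 1/se²`; heterogeneity by Cochran's
  `Q = Σw(β − β̂)²` on k−1 df.
* **Attenuation:** weighted regression through the origin of cohort
  log-ORs on reference log-ORs, `slope = Σwxy/Σwx²`, `w = 1/se_y²`;
  the proportional reduction in log-OR is `1 − slope`.
* **GRS:** `GRS = Σ wᵢ gᵢ` with `wᵢ = ln ORᵢ`, rescaled by
  `2M/(2Σw)` so one point averages one risk allele; floating absolute
  risks give every score quartile (including the reference) its own
  variance.
* **Discrimination:** C-statistic `P(score_case > score_control) + ½P(tie)`
  with DeLong structural-components variance and paired tests.
* **Interaction:** logistic model with GRS, adiposity measure and their
  product, Wald test of the product term; WHO Asian BMI classes and
  sex-specific tertiles define strata.

## Worked example

Pooling the bundled published summary statistics (56 variants; cohort +
East Asian consortium columns) and running the concordance tests:

```sh
Rscript analysis/01_meta_analysis_table.R
```

prints

```
pooled ORs within +-0.01 of the published value: 55 of 55
heterogeneity beyond the Bonferroni threshold (3.0e-4): ZFAND3
concordance 48/56: one-sided binomial p = 2.34e-08
concordance 37/40: one-sided binomial p = 9.73e-09
```

i.e. every pooled OR recomputed from the printed per-study CIs matches the
published pooled column to ±0.01, exactly one locus shows between-study
heterogeneity beyond the Bonferroni threshold, and the directional
concordance of cohort effects with discovery reports is overwhelmingly
non-random.  The remaining scripts run the synthetic end-to-end study
(02 simulation → 03 QC + association → 04 winner's curse → 05 GRS +
ROC → 06 strata/interaction); on the default 20,000-individual cohort,
script 05 prints

```
top vs bottom weighted-GRS quartile: OR 2.39 (2.18, 2.62)
C statistic: unweighted 0.568 (0.554, 0.583); weighted 0.591 (0.576, 0.606)
DeLong weighted vs unweighted: delta C = 0.0227, p = 1.91e-05
```

— the weighted score discriminates significantly better than the allele
count, and the extreme-quartile contrast is of the size expected for a
~50-SNP diabetes score.  Script 04 demonstrates the winner's curse
directly: discovery replicates selected at p < 5×10⁻⁸ overestimate a true
log-OR of 0.113 by ~40% on average, and the through-origin regression of
unbiased re-estimates on selected estimates recovers the attenuation
(slope < 1) with high confidence.

Stage outputs are written as TSVs under `results/`.

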