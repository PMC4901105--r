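#' Hardy-Weinberg equilibrium 1-df chi-square test
#'
#' Compares observed genotype counts with the Hardy-Weinberg expectation
#' `n * (p^2, 2pq, q^2)` at the estimated allele frequency, on 1 df.
#' Monomorphic SNPs are flagged and returned as `chi2 = 0, p = 1` rather
#' than erroring.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (AA = two copies of the first
#'   allele).  Vectorised.
#' @return Data frame with `chi2`, `p` and `monomorphic`.
#' @export
#' @examples
#' hwe_chi2_test(30, 40, 30)   # chi2 = 4, p ~ 0.0455
hwe_chi2_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) stop("need at least one genotyped individual")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  mono <- p == 0 | p == 1
  exp_AA <- n * p^2
  exp_Aa <- n * 2 * p * (1 - p)
  exp_aa <- n * (1 - p)^2
  chi2 <- ifelse(mono, 0,
                 (n_AA - exp_AA)^2 / pmax(exp_AA, .Machine$double.eps) +
                 (n_Aa - exp_Aa)^2 / pmax(exp_Aa, .Machine$double.eps) +
                 (n_aa - exp_aa)^2 / pmax(exp_aa, .Machine$double.eps))
  data.frame(chi2 = chi2,
             p = ifelse(mono, 1, stats::pchisq(chi2, 1, lower.tail = FALSE)),
             monomorphic = mono)
}

#' Per-SNP quality control
#'
#' Removes SNPs with call rate below `call_threshold` or Hardy-Weinberg
#' disequilibrium p below `hwe_threshold`.  Defaults follow array-QC
#' convention for a 384-SNP panel: call rate < 95% and Bonferroni-corrected
#' HWE p < 0.05/384 = 1.3e-4.
#'
#' @param G Dosage matrix (0/1/2/NA), SNPs in columns.
#' @param call_threshold Minimum per-SNP call rate.
#' @param hwe_threshold HWE p-value below which a SNP is removed.
#' @return Data frame with per-SNP `snp_id`, `call_rate`, genotype counts,
#'   `hwe_chi2`, `hwe_p`, `monomorphic` and `kept`.
#' @export
snp_qc <- function(G, call_threshold = 0.95, hwe_threshold = 1.3e-4) {
  if (is.null(dim(G)) || ncol(G) == 0) stop("G must be a non-empty matrix")
  call_rate <- colMeans(!is.na(G))
  n_AA <- colSums(G == 2, na.rm = TRUE)
  n_Aa <- colSums(G == 1, na.rm = TRUE)
  n_aa <- colSums(G == 0, na.rm = TRUE)
  hwe <- hwe_chi2_test(n_AA, n_Aa, n_aa)
  data.frame(snp_id = colnames(G), call_rate = call_rate,
             n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
             hwe_chi2 = hwe$chi2, hwe_p = hwe$p,
             monomorphic = hwe$monomorphic,
             kept = call_rate >= call_threshold & hwe$p >= hwe_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample quality control
#'
#' Computes per-sample call rate and the heterozygosity-based inbreeding
#' coefficient `F = 1 - observed het / expected het`, where the expected
#' heterozygosity sums `2 p (1 - p)` over that sample's observed SNPs with
#' allele frequencies estimated from the full matrix.  Samples are removed
#' when the call rate falls below `call_threshold` or the robust z-score of
#' F (median/MAD with the 1.4826 consistency factor) reaches
#' `f_zscore_threshold` in absolute value.
#'
#' @param G Dosage matrix (0/1/2/NA), samples in rows.
#' @param call_threshold Minimum per-sample call rate.
#' @param f_zscore_threshold Threshold on `|robust z(F)|`.
#' @return Data frame with `sample_id`, `call_rate`, `het_obs`, `het_exp`,
#'   `F`, `f_z` and `kept`.
#' @export
sample_qc <- function(G, call_threshold = 0.98, f_zscore_threshold = 5) {
  if (nrow(G) < 2) stop("need at least 2 samples")
  call_rate <- rowMeans(!is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  hexp_snp <- 2 * p * (1 - p)
  obs <- !is.na(G)
  het_obs <- rowSums(G == 1, na.rm = TRUE)
  het_exp <- obs %*% hexp_snp
  F <- ifelse(het_exp > 0, 1 - het_obs / het_exp, 0)
  md <- stats::median(F)
  s <- stats::mad(F)  # median absolute deviation * 1.4826
  f_z <- if (s > 0) (F - md) / s else rep(0, length(F))
  kept <- call_rate >= call_threshold & abs(f_z) < f_zscore_threshold
  if (!any(kept)) stop("sample QC removed every sample")
  data.frame(sample_id = rownames(G), call_rate = call_rate,
             het_obs = het_obs, het_exp = drop(het_exp), F = drop(F),
             f_z = drop(f_z), kept = kept,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify diabetes status from self-report and glucose screening
#'
#' Implements the case-definition rules: self-reported physician-diagnosed
#' diabetes with onset under age 30 and current insulin treatment is
#' classified as type 1 (`type1_excluded`); other self-reports are
#' `prevalent_selfreport`; otherwise `screen_detected` if any applicable
#' rule holds -- random glucose >= 7.0 mmol/l with fasting time > 8 h,
#' random glucose >= 11.1 mmol/l with fasting time < 8 h, or fasting
#' glucose >= 7.0 mmol/l; else `control`.  A fasting time of exactly 8 h
#' satisfies neither random-glucose rule by default (the rules are stated
#' as strict inequalities); set `eight_hours_fasted = TRUE` to count
#' exactly 8 h as fasted.
#'
#' @param pheno Data frame with columns `self_report_diabetes`,
#'   `age_at_onset`, `insulin_treated`, `random_glucose`, `fasting_glucose`,
#'   `fasting_time` (absent columns are treated as all-`NA`).
#' @param eight_hours_fasted Treat fasting time exactly 8 h as > 8 h.
#' @return Character vector of statuses, one per row.
#' @export
classify_diabetes_status <- function(pheno, eight_hours_fasted = FALSE) {
  get <- function(nm, default = NA) {
    if (nm %in% names(pheno)) pheno[[nm]] else rep(default, nrow(pheno))
  }
  sr <- get("self_report_diabetes")
  onset <- get("age_at_onset")
  ins <- get("insulin_treated")
  rg <- get("random_glucose")
  fg <- get("fasting_glucose")
  ft <- get("fasting_time")
  if (any(is.na(sr) & is.na(rg) & is.na(fg)))
    stop("at least one of self-report / glucose fields must be present")
  if (any(c(rg[!is.na(rg)], fg[!is.na(fg)]) < 0))
    stop("glucose values must be non-negative")
  long_fast <- if (eight_hours_fasted) !is.na(ft) & ft >= 8 else !is.na(ft) & ft > 8
  short_fast <- !is.na(ft) & ft < 8
  screen <- (!is.na(rg) & rg >= 7.0 & long_fast) |
            (!is.na(rg) & rg >= 11.1 & short_fast) |
            (!is.na(fg) & fg >= 7.0)
  status <- rep("control", nrow(pheno))
  status[screen] <- "screen_detected"
  is_sr <- !is.na(sr) & sr
  status[is_sr] <- "prevalent_selfreport"
  t1 <- is_sr & !is.na(onset) & onset < 30 & !is.na(ins) & ins
  status[t1] <- "type1_excluded"
  status
}
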