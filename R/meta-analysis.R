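#' Recover a log-OR and its SE from a printed OR and 95% CI
#'
#' `beta = ln(or_)`; `se = (ln(hi) - ln(lo)) / (2 * 1.959964)`.  The exact
#' normal quantile (not 1.96) is used throughout the package: the difference
#' matters when pooled ORs are compared with printed tables at +-0.01.
#'
#' @param or_ Point odds ratio.
#' @param lo,hi Confidence limits, `0 < lo <= or_ <= hi`.
#' @param level Confidence level of the printed interval.
#' @return Data frame with `beta` and `se` (vectorised).
#' @export
#' @examples
#' se_from_ci(2.0, 1.0, 4.0)   # beta = ln 2, se ~ 0.3536
se_from_ci <- function(or_, lo, hi, level = 0.95) {
  if (any(lo <= 0 | lo > or_ | or_ > hi)) stop("require 0 < lo <= or_ <= hi")
  if (any(lo == hi)) stop("zero-width confidence interval")
  # 1.959964 is used for the 95% level everywhere in the package so that
  # CI construction and recovery are exact inverses
  zq <- if (level == 0.95) 1.959964 else stats::qnorm(1 - (1 - level) / 2)
  data.frame(beta = log(or_), se = (log(hi) - log(lo)) / (2 * zq))
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools study log-ORs with weights `w = 1/se^2`:
#' `beta_pooled = sum(w b) / sum(w)`, `se_pooled = 1/sqrt(sum(w))`, with a
#' Wald 95% CI and two-sided p.  Cochran's Q and its heterogeneity p are
#' included whenever two or more studies are pooled.
#'
#' @param beta Study log-ORs.
#' @param se Study standard errors (> 0).
#' @param snp_id Label carried into the result.
#' @return One-row data frame (`snp_id`, `n_studies`, `beta_pooled`,
#'   `se_pooled`, `or_`, `ci_low`, `ci_high`, `p`, `Q`, `df`, `p_het`).
#' @export
ivw_fixed_meta <- function(beta, se, snp_id = NA_character_) {
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  if (any(!is.finite(se) | se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  sp <- 1 / sqrt(sum(w))
  zq <- 1.959964
  k <- length(beta)
  Q <- if (k >= 2) sum(w * (beta - bp)^2) else NA_real_
  data.frame(snp_id = snp_id, n_studies = k, beta_pooled = bp,
             se_pooled = sp, or_ = exp(bp), ci_low = exp(bp - zq * sp),
             ci_high = exp(bp + zq * sp),
             p = 2 * stats::pnorm(-abs(bp / sp)),
             Q = Q, df = k - 1L,
             p_het = if (k >= 2) stats::pchisq(Q, k - 1, lower.tail = FALSE)
                     else NA_real_,
             stringsAsFactors = FALSE)
}

#' Cochran's Q test of between-study heterogeneity
#'
#' `Q = sum(w (beta - beta_pooled)^2)` with `w = 1/se^2`, chi-square
#' distributed with `k - 1` df under homogeneity.  The conventional
#' significance threshold in this pipeline is the Bonferroni-corrected
#' 0.05/(55*3) = 3.0e-4 used when testing heterogeneity across a 55-SNP
#' panel under three comparisons.
#'
#' @inheritParams ivw_fixed_meta
#' @return List with `Q`, `df`, `p_het`.
#' @export
cochran_q <- function(beta, se) {
  if (length(beta) < 2) stop("need at least 2 estimates")
  if (any(!is.finite(se) | se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bp)^2)
  list(Q = Q, df = length(beta) - 1L,
       p_het = stats::pchisq(Q, length(beta) - 1, lower.tail = FALSE))
}

#' Meta-analyse a table of per-SNP study estimates
#'
#' Accepts rows with either (`beta`, `se`) or a printed (`or_`, `ci_low`,
#' `ci_high`) triple -- the latter are converted with [se_from_ci()] -- and
#' pools within `snp_id` by [ivw_fixed_meta()].
#'
#' @param estimates Data frame with columns `snp_id`, `study`, and either
#'   `beta` + `se` or `or_` + `ci_low` + `ci_high`.
#' @return Data frame with one pooled row per SNP.
#' @export
meta_scan <- function(estimates) {
  if (!all(c("beta", "se") %in% names(estimates))) {
    conv <- se_from_ci(estimates$or_, estimates$ci_low, estimates$ci_high)
    estimates$beta <- conv$beta
    estimates$se <- conv$se
  }
  out <- lapply(split(estimates, estimates$snp_id), function(d) {
    ivw_fixed_meta(d$beta, d$se, snp_id = d$snp_id[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
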