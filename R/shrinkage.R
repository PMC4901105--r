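#' Effect-size attenuation by weighted regression through the origin
#'
#' Regresses population-cohort log-ORs (`y`) on reference (discovery or
#' external meta-analysis) log-ORs (`x`) through the origin, with weights
#' `1/y_se^2` (only the target-estimate uncertainty enters the weights).
#' `slope = sum(w x y) / sum(w x^2)`, `slope_se = 1/sqrt(sum(w x^2))`.  The
#' headline statistic is the proportional reduction in log-OR,
#' `1 - slope`, with a Wald 95% CI and a test of slope = 1.  Pearson
#' correlation of the paired effects is reported alongside.
#'
#' @param x Reference log-ORs.
#' @param y Target (population cohort) log-ORs.
#' @param y_se Standard errors of `y` (> 0).
#' @return One-row data frame (`slope`, `slope_se`, `reduction`,
#'   `reduction_lo`, `reduction_hi`, `p_vs_unity`, `r`, `n_snps`).
#' @export
through_origin_wls <- function(x, y, y_se) {
  stopifnot(length(x) == length(y), length(y) == length(y_se))
  if (length(x) < 2) stop("need at least 2 effect pairs")
  if (all(x == 0)) stop("all reference effects are zero")
  if (any(!is.finite(y_se) | y_se <= 0)) stop("y_se must be positive")
  w <- 1 / y_se^2
  slope <- sum(w * x * y) / sum(w * x^2)
  slope_se <- 1 / sqrt(sum(w * x^2))
  zq <- 1.959964
  z <- (1 - slope) / slope_se
  data.frame(slope = slope, slope_se = slope_se,
             reduction = 1 - slope,
             reduction_lo = 1 - (slope + zq * slope_se),
             reduction_hi = 1 - (slope - zq * slope_se),
             p_vs_unity = 2 * stats::pnorm(-abs(z)),
             r = if (length(x) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
                   stats::cor(x, y) else NA_real_,
             n_snps = length(x))
}

#' Pearson correlation of paired effect sizes
#'
#' @param x,y Paired log-ORs (>= 3 pairs, non-degenerate).
#' @return Correlation coefficient.
#' @export
effect_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in effects")
  stats::cor(x, y)
}
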