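#' Adiposity stratification schemes
#'
#' Two modes are supported.  `fixed_cutpoints` applies absolute cut-points
#' (default: WHO Asian BMI classes -- normal < 23, overweight 23 to < 27.5,
#' obese >= 27.5 kg/m^2; boundary values fall in the upper class, matching
#' the class definitions).  `sex_specific_tertiles` computes tertile
#' boundaries within each sex on the analysis sample; values equal to a
#' tertile boundary are assigned to the lower tertile.
#'
#' @param values Numeric adiposity variable.
#' @param sex Sex per individual (required for tertile mode).
#' @param mode `"fixed_cutpoints"` or `"sex_specific_tertiles"`.
#' @param cutpoints Increasing cut-points for fixed mode.
#' @param labels Stratum labels, `length(cutpoints) + 1` (fixed mode) or 3
#'   (tertile mode).
#' @return Factor of stratum labels.
#' @export
#' @examples
#' define_strata(c(22.9, 23, 27.5))  # normal, overweight, obese
define_strata <- function(values, sex = NULL,
                          mode = c("fixed_cutpoints", "sex_specific_tertiles"),
                          cutpoints = c(23, 27.5),
                          labels = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(values))) stop("values must be finite")
  if (mode == "fixed_cutpoints") {
    if (is.unsorted(cutpoints, strictly = TRUE))
      stop("cutpoints must be strictly increasing")
    if (is.null(labels)) {
      labels <- if (length(cutpoints) == 2 && all(cutpoints == c(23, 27.5)))
        c("normal", "overweight", "obese")
      else paste0("S", seq_len(length(cutpoints) + 1))
    }
    return(cut(values, c(-Inf, cutpoints, Inf), labels = labels,
               right = FALSE))
  }
  if (is.null(sex)) stop("sex is required for sex-specific tertiles")
  if (is.null(labels)) labels <- c("low", "medium", "high")
  out <- factor(rep(NA_character_, length(values)), levels = labels)
  for (s in unique(sex)) {
    idx <- sex == s
    v <- values[idx]
    if (length(unique(v)) < 3)
      stop("constant or near-constant variable within sex ", s)
    qs <- stats::quantile(v, c(1, 2) / 3, type = 7)
    # ties on a boundary go to the lower tertile: intervals (-Inf,q1],(q1,q2],(q2,Inf)
    out[idx] <- labels[findInterval(v, qs, left.open = TRUE) + 1L]
  }
  out
}

#' Stratified GRS-diabetes association
#'
#' Independent covariate-adjusted logistic fits of the outcome on the
#' rescaled GRS within each stratum; the OR is per rescaled GRS point.
#' Strata containing a single outcome class are flagged and omitted.
#'
#' @param score Rescaled GRS.
#' @param y Binary outcome.
#' @param covariates Optional covariate data frame.
#' @param labels Stratum factor from [define_strata()].
#' @return Data frame with one row per stratum (`stratum`, `n_cases`,
#'   `n_controls`, `beta`, `se`, `or_`, `ci_low`, `ci_high`, `p`).
#' @export
stratified_grs_association <- function(score, y, covariates = NULL, labels) {
  stopifnot(length(labels) == length(y))
  out <- lapply(levels(droplevels(as.factor(labels))), function(l) {
    idx <- which(labels == l)
    if (length(unique(y[idx])) < 2) {
      warning("stratum ", l, " has a single outcome class; omitted")
      return(NULL)
    }
    fit <- fit_snp_logistic(score[idx], y[idx],
                            if (is.null(covariates)) NULL
                            else droplevels_df(covariates[idx, , drop = FALSE]),
                            snp_id = l)
    data.frame(stratum = l, n_cases = sum(y[idx] == 1),
               n_controls = sum(y[idx] == 0), beta = fit$beta, se = fit$se,
               or_ = fit$or_, ci_low = fit$ci_low, ci_high = fit$ci_high,
               p = fit$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

droplevels_df <- function(df) {
  df[] <- lapply(df, function(x) if (is.factor(x)) droplevels(x) else x)
  df
}

#' GRS-by-adiposity interaction test
#'
#' Single covariate-adjusted logistic model containing the GRS, the
#' adiposity variable and their product; the interaction p is the Wald test
#' of the product term.  The variable may be continuous (primary analysis)
#' or an ordinal stratum coding (secondary); both conventions appear in the
#' literature and both are supported here.
#'
#' @param score Rescaled GRS.
#' @param variable Continuous adiposity measure, or ordinal-coded strata.
#' @param y Binary outcome.
#' @param covariates Optional covariate data frame.
#' @return One-row data frame (`beta_grs`, `beta_var`, `beta_interaction`,
#'   `se_interaction`, `p_interaction`).
#' @export
grs_interaction_test <- function(score, variable, y, covariates = NULL) {
  if (is.factor(variable)) variable <- as.numeric(variable)
  dat <- data.frame(y = y, grs = score, v = variable)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- stats::glm(y ~ . + grs:v, family = stats::binomial(), data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("collinear terms in interaction model: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  sm <- summary(fit)$coefficients
  data.frame(beta_grs = sm["grs", 1], beta_var = sm["v", 1],
             beta_interaction = sm["grs:v", 1],
             se_interaction = sm["grs:v", 2],
             p_interaction = 2 * stats::pnorm(-abs(sm["grs:v", 1] /
                                                     sm["grs:v", 2])))
}

#' Linear association of a continuous trait with the GRS
#'
#' Covariate-adjusted least-squares slope of the trait on the rescaled GRS
#' (used e.g. to test whether a beta-cell score is inversely associated
#' with adiposity measures).
#'
#' @param score Rescaled GRS.
#' @param trait Continuous trait.
#' @param covariates Optional covariate data frame.
#' @return One-row data frame (`slope`, `se`, `p`, `n`).
#' @export
grs_trait_association <- function(score, trait, covariates = NULL) {
  if (stats::sd(trait) == 0 || stats::sd(score) == 0)
    stop("zero variance in trait or score")
  dat <- data.frame(trait = trait, grs = score)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- stats::lm(trait ~ ., data = dat)
  sm <- summary(fit)$coefficients
  data.frame(slope = sm["grs", 1], se = sm["grs", 2], p = sm["grs", 4],
             n = length(trait))
}
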