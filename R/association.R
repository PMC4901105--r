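#' Covariate-adjusted per-SNP logistic association
#'
#' Maximum-likelihood per-allele log-OR for a 0/1/2 dosage with Wald SE,
#' 95% CI (z = 1.959964) and Wald p, adjusting for any supplied covariates
#' (factors such as regional centre enter as indicator terms).  Separation
#' and non-convergence are detected and flagged, never silently returned.
#'
#' @param dosage Numeric dosage vector (no missing values; impute or drop
#'   upstream).
#' @param y Binary 0/1 outcome.
#' @param covariates Optional data frame of covariates.
#' @param snp_id Label carried into the result.
#' @return One-row data frame (`snp_id`, `n_used`, `beta`, `se`, `or_`,
#'   `ci_low`, `ci_high`, `p`, `raf_observed`, `converged`, `flagged`).
#' @export
fit_snp_logistic <- function(dosage, y, covariates = NULL, snp_id = "snp") {
  if (anyNA(dosage)) stop("dosage must not contain missing values")
  stopifnot(length(dosage) == length(y), all(y %in% 0:1))
  dat <- data.frame(y = y, g = dosage)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
  }
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = dat))
  sm <- summary(fit)$coefficients
  beta <- sm["g", 1]; se <- sm["g", 2]
  zq <- 1.959964
  flagged <- !fit$converged || !is.finite(se) || se > 50 || abs(beta) > 15
  data.frame(snp_id = snp_id, n_used = length(y), beta = beta, se = se,
             or_ = exp(beta), ci_low = exp(beta - zq * se),
             ci_high = exp(beta + zq * se),
             p = 2 * stats::pnorm(-abs(beta / se)),
             raf_observed = mean(dosage) / 2,
             converged = fit$converged, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Association scan over a dosage matrix
#'
#' Applies [fit_snp_logistic()] column-wise; individuals missing a SNP's
#' dosage are dropped for that SNP.
#'
#' @param G Dosage matrix, SNPs in columns.
#' @inheritParams fit_snp_logistic
#' @return Data frame with one row per SNP.
#' @export
assoc_scan <- function(G, y, covariates = NULL) {
  res <- lapply(seq_len(ncol(G)), function(j) {
    ok <- !is.na(G[, j])
    fit_snp_logistic(G[ok, j], y[ok],
                     if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE],
                     snp_id = colnames(G)[j])
  })
  do.call(rbind, res)
}

#' Exact binomial test of directional concordance
#'
#' Counts agreements between observed and reference effect directions and
#' returns the exact one-sided binomial tail `P(X >= k | n, 1/2)`.  The
#' one-sided tail is what published concordance p-values for replication of
#' GWAS directions correspond to, and is documented as such.
#'
#' @param signs_observed,signs_reference Vectors of +1/-1.
#' @return List with `k_concordant`, `n`, `p`.
#' @export
#' @examples
#' sign_concordance_test(rep(1, 10), c(rep(1, 5), rep(-1, 5)))  # p = 0.623
sign_concordance_test <- function(signs_observed, signs_reference) {
  stopifnot(length(signs_observed) == length(signs_reference))
  n <- length(signs_observed)
  if (n == 0) stop("no effects to compare")
  if (any(signs_observed == 0 | signs_reference == 0))
    stop("zero signs are not allowed")
  k <- sum(sign(signs_observed) == sign(signs_reference))
  list(k_concordant = k, n = n,
       p = stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

#' Genomic inflation factor and its 1000-case/1000-control rescaling
#'
#' `lambda_obs` is the median association chi-square divided by the
#' theoretical chi-square(1) median (0.4549364); `lambda_1000` rescales it
#' to an equivalent study of 1,000 cases and 1,000 controls:
#' `1 + (lambda_obs - 1) * (1/n_cases + 1/n_controls) / (2/1000)`.
#'
#' @param chi2_stats Vector of per-SNP 1-df association chi-squares (>= 10).
#' @param n_cases,n_controls Raw case and control counts.
#' @return Data frame (`lambda_obs`, `lambda_1000`, `n_cases`, `n_controls`,
#'   `n_snps_used`).
#' @export
genomic_inflation <- function(chi2_stats, n_cases, n_controls) {
  if (length(chi2_stats) < 10) stop("need at least 10 statistics")
  if (any(chi2_stats < 0)) stop("chi-square statistics must be non-negative")
  lambda_obs <- stats::median(chi2_stats) / 0.4549364
  lambda_1000 <- 1 + (lambda_obs - 1) *
    (1 / n_cases + 1 / n_controls) / (2 / 1000)
  data.frame(lambda_obs = lambda_obs, lambda_1000 = lambda_1000,
             n_cases = n_cases, n_controls = n_controls,
             n_snps_used = length(chi2_stats))
}

#' Multiple-testing adjustment (Holm step-down or Benjamini-Hochberg step-up)
#'
#' Thin, validated wrapper over [stats::p.adjust()]: monotonicity is
#' enforced and values capped at 1 by the underlying procedures.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"holm"` (family-wise error) or `"bh"` (false discovery
#'   rate).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "holm")
}

# Per-SNP score-test z-statistics for adding each dosage column to a null
# logistic model y ~ covariates.  One null fit serves all SNPs, which makes
# phenotype permutations cheap.
score_z <- function(G, y, covariates = NULL) {
  n <- length(y)
  if (is.null(covariates)) {
    # intercept-only null model: fitted probability is the phenotype mean
    X <- matrix(1, n, 1)
    mu <- rep(mean(y), n)
  } else {
    X <- stats::model.matrix(~ ., data = covariates)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    mu <- fit$fitted.values
  }
  w <- mu * (1 - mu)
  U <- drop(crossprod(G, y - mu))
  XtWX_inv <- solve(crossprod(X, X * w))
  GtWX <- crossprod(G, X * w)
  V <- colSums(G * G * w) - rowSums((GtWX %*% XtWX_inv) * GtWX)
  U / sqrt(V)
}

#' Permutation-based family-wise error control (max-|z| procedure)
#'
#' Computes per-SNP score-test z-statistics under the null logistic model
#' `y ~ covariates`, then permutes the phenotype (covariates held fixed),
#' recording the maximum |z| over SNPs for each permutation.  The adjusted
#' p-value for each SNP is `(1 + #{perm max >= |z_obs|}) / (n_perm + 1)`.
#'
#' @param dosages Complete dosage matrix, SNPs in columns.
#' @param y Binary outcome.
#' @param covariates Optional covariate data frame.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return Data frame (`snp_id`, `z_obs`, `p_adjusted`).
#' @export
permutation_fwer <- function(dosages, y, covariates = NULL,
                             n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(dosages)) stop("dosages must be complete")
  z_obs <- abs(score_z(dosages, y, covariates))
  max_perm <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    if (length(unique(yp)) < 2) stop("degenerate phenotype after permutation")
    max(abs(score_z(dosages, yp, covariates)))
  }, numeric(1))
  p_adj <- vapply(z_obs, function(z) {
    (1 + sum(max_perm >= z)) / (n_perm + 1)
  }, numeric(1))
  data.frame(snp_id = colnames(dosages), z_obs = z_obs,
             p_adjusted = p_adj, row.names = NULL, stringsAsFactors = FALSE)
}
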