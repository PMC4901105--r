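# Independent oracles used across the suite.  Everything here is computed
# from first principles (enumeration, closed forms, grid search) and never
# calls the package functions it is used to check.

# Exact Hardy-Weinberg test (Levene/Haldane conditional distribution of the
# heterozygote count given allele counts); returns the exact p-value.
exact_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  sum(p[p <= p[hets == n_Aa] * (1 + 1e-12)])
}

# Grid-search ML for the no-covariate logistic model on a collapsed
# dosage x outcome count table; three refinement stages.
gridsearch_logistic <- function(cases, controls) {
  loglik <- function(a, b) {
    g <- 0:2
    eta <- a + b * g
    sum(cases * eta - (cases + controls) * log1p(exp(eta)))
  }
  a0 <- 0; b0 <- 0; half_a <- 6; half_b <- 3
  for (stage in 1:6) {
    as <- seq(a0 - half_a, a0 + half_a, length.out = 41)
    bs <- seq(b0 - half_b, b0 + half_b, length.out = 41)
    ll <- outer(as, bs, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    a0 <- as[best[1]]; b0 <- bs[best[2]]
    half_a <- half_a / 10; half_b <- half_b / 10
  }
  c(intercept = a0, beta = b0)
}

# Definition-based Holm (step-down) and BH (step-up) adjustments.
brute_holm <- function(p) {
  n <- length(p); o <- order(p)
  adj <- numeric(n); run <- 0
  for (i in seq_len(n)) {
    run <- max(run, (n - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}
brute_bh <- function(p) {
  n <- length(p); o <- order(p, decreasing = TRUE)
  adj <- numeric(n); run <- Inf
  for (i in seq_len(n)) {
    rank_i <- n - i + 1
    run <- min(run, n / rank_i * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# Full pair-enumeration C-statistic and DeLong structural components.
enum_c <- function(scores, y) {
  ca <- scores[y == 1]; co <- scores[y == 0]
  psi <- outer(ca, co, function(a, b) (a > b) + 0.5 * (a == b))
  list(theta = mean(psi),
       V10 = rowMeans(psi), V01 = 1 - colMeans(psi),
       m = length(ca), n = length(co))
}
enum_delong_var <- function(scores, y) {
  e <- enum_c(scores, y)
  stats::var(e$V10) / e$m + stats::var(e$V01) / e$n
}
enum_delong_test <- function(a, b, y) {
  ea <- enum_c(a, y); eb <- enum_c(b, y)
  s10 <- stats::cov(cbind(ea$V10, eb$V10))
  s01 <- stats::cov(cbind(ea$V01, eb$V01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ea$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ea$n
  list(delta = ea$theta - eb$theta, var = v)
}

# Closed-form normal-equations slope for trait ~ score + covariates.
normal_eq_slope <- function(trait, score, covariates = NULL) {
  X <- cbind(1, score)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  unname(drop(solve(crossprod(X), crossprod(X, trait)))[2])
}

# Small null cohort used by several calibration tests.
null_cohort <- function(n, n_snps, raf = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(rbinom(n * n_snps, 2, raf), n, n_snps,
              dimnames = list(NULL, paste0("s", seq_len(n_snps))))
  y <- rbinom(n, 1, 0.3)
  list(G = G, y = y)
}
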