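test_that("centre-mean imputation fills with the within-centre mean", {
  G <- rbind(c(0L, 2L), c(2L, NA), c(NA, 1L), c(1L, 1L))
  rownames(G) <- paste0("i", 1:4); colnames(G) <- c("s1", "s2")
  centre <- c("A", "A", "B", "B")
  r <- impute_missing_by_centre_mean(G, centre)
  expect_equal(r$G["i3", "s1"], 1)    # centre B mean of s1 = 1
  expect_equal(r$G["i2", "s2"], 2)    # centre A mean of s2 = 2
  expect_equal(r$n_imputed, c(0L, 1L, 1L, 0L))

  # centre with no observed calls falls back to the overall mean
  G2 <- rbind(c(0L), c(2L), c(NA), c(NA))
  rownames(G2) <- paste0("i", 1:4); colnames(G2) <- "s1"
  expect_warning(r2 <- impute_missing_by_centre_mean(G2, c("A", "A", "B", "B")),
                 "overall mean")
  expect_equal(unname(r2$G[3:4, 1]), c(1, 1))
  # complete input is returned unchanged
  r3 <- impute_missing_by_centre_mean(G[1:2, 1, drop = FALSE], c("A", "A"))
  expect_equal(unname(r3$G), unname(G[1:2, 1, drop = FALSE]) + 0)
  expect_identical(dimnames(r3$G), dimnames(G[1:2, 1, drop = FALSE]))
  expect_error(impute_missing_by_centre_mean(
    matrix(NA_integer_, 2, 1, dimnames = list(NULL, "s")), c("A", "B")),
    "no observed")
})

test_that("GRS rescaling makes one point one average risk allele", {
  G <- rbind(c(2, 1), c(0, 2), c(1, 0))
  colnames(G) <- c("a", "b")
  # worked example: weights (0.1, 0.3), dosages (2, 1)
  r <- compute_grs(G, c("a", "b"), c(a = 0.1, b = 0.3))
  expect_equal(r$raw[1], 0.5, tolerance = 1e-12)
  expect_equal(r$rescaled[1], 0.5 * 4 / (2 * 0.4), tolerance = 1e-12)
  # equal weights: rescaled equals the allele count exactly
  u <- compute_grs(G, c("a", "b"), 1)
  expect_equal(u$rescaled, rowSums(G), tolerance = 1e-12)
  expect_equal(u$raw, u$rescaled)
  expect_error(compute_grs(G, c("a", "b"), c(a = -1, b = 0.5)), "positive")
  expect_error(compute_grs(G, c("a", "z"), 1), "absent")
})

test_that("raw and rescaled scores give identical association z-statistics", {
  set.seed(101)
  n <- 2000
  G <- matrix(rbinom(n * 10, 2, 0.4), n, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  w <- setNames(runif(10, 0.05, 0.3), colnames(G))
  prof <- compute_grs(G, colnames(G), w)
  y <- rbinom(n, 1, plogis(-2 + 0.1 * prof$rescaled))
  f_raw <- fit_snp_logistic(prof$raw, y)
  f_res <- fit_snp_logistic(prof$rescaled, y)
  expect_equal(f_raw$beta / f_raw$se, f_res$beta / f_res$se, tolerance = 1e-6)
  expect_equal(f_raw$p, f_res$p, tolerance = 1e-6)
  # equal weights rank individuals identically to the unweighted count
  # (up to floating-point noise in the rescaling factor)
  ueq <- compute_grs(G, colnames(G), 0.37)
  expect_equal(ueq$rescaled, rowSums(G) + 0, tolerance = 1e-12)
  expect_equal(rank(round(ueq$rescaled, 9)), rank(rowSums(G)))
})

test_that("mechanism classification follows the evidence hierarchy", {
  ev <- data.frame(
    homa_b_decreased        = c(TRUE,  FALSE, FALSE, FALSE, TRUE),
    ogtt_bc_index           = FALSE,
    bc_cluster              = FALSE,
    monogenic_locus         = FALSE,
    homa_ir_increased       = c(FALSE, FALSE, FALSE, TRUE,  TRUE),
    fasting_insulin_up      = c(FALSE, TRUE,  FALSE, FALSE, FALSE),
    ir_cluster              = FALSE,
    triacylglycerol_ir_trait = FALSE,
    obesity_mediated        = c(FALSE, FALSE, FALSE, TRUE,  FALSE))
  expect_identical(classify_mechanism(ev),
                   c("BC", "IR", "unclassified", "unclassified", "BC"))
  # tie-break is configurable
  expect_identical(classify_mechanism(ev, prefer = "IR")[5], "IR")
})

test_that("variance explained follows the plug-in formula and is monotone", {
  expect_equal(variance_explained(0, 0.02, 0.3, 1e4), 0)
  b <- 0.1; se <- 0.02; p <- 0.3; n <- 1e4
  num <- 2 * b^2 * p * (1 - p)
  expect_equal(variance_explained(b, se, p, n),
               num / (num + se^2 * 2 * n * p * (1 - p)), tolerance = 1e-6)
  pve <- variance_explained(seq(0.01, 0.5, by = 0.01), 0.02, 0.3, 1e4)
  expect_true(all(diff(pve) > 0))
  expect_error(variance_explained(0.1, 0.02, 0, 1e4), "strictly")
})

test_that("floated variances reproduce pairwise contrast variances", {
  # two-level case is exact
  set.seed(102)
  n <- 4000
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * (score > 0)))
  grp <- factor(ifelse(score > 0, "high", "low"), levels = c("low", "high"))
  fit <- glm(y ~ grp, family = binomial())
  V <- matrix(0, 2, 2); V[2, 2] <- vcov(fit)["grphigh", "grphigh"]
  fl <- t2dgrs:::floated_variances(V)
  expect_equal(unname(fl[1] + fl[2]), V[2, 2], tolerance = 1e-9)

  # four simulated quartiles with monotone risk: all contrasts within 5%
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.4 * score))
  qa <- quartile_association(score, y)
  V <- qa$vcov; fl <- qa$table$float_var
  for (i in 1:3) for (j in (i + 1):4) {
    cv <- V[i, i] + V[j, j] - 2 * V[i, j]
    expect_lt(abs((fl[i] + fl[j]) - cv) / cv, 0.05)
  }
  # null score: quartile ORs all near 1
  y0 <- rbinom(n, 1, 0.3)
  qa0 <- quartile_association(rnorm(n), y0)
  expect_true(all(abs(log(qa0$table$or_)) < 0.35))
  expect_error(quartile_association(rep(1:2, 50), rbinom(100, 1, 0.5)),
               "distinct")
})

test_that("correctly weighted GRS discriminates at least as well as unweighted", {
  set.seed(103)
  wins <- vapply(1:10, function(r) {
    n <- 20000; p <- 50
    beta <- runif(p, log(1.02), log(1.30))
    raf <- runif(p, 0.1, 0.9)
    G <- sapply(raf, function(f) rbinom(n, 2, f))
    colnames(G) <- paste0("s", 1:p)
    y <- rbinom(n, 1, plogis(-3 + drop(G %*% beta)))
    w <- compute_grs(G, colnames(G), setNames(beta, colnames(G)))$rescaled
    u <- compute_grs(G, colnames(G), 1)$rescaled
    dl <- delong_test(w, u, y)
    dl$delta_c >= 0
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
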