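test_that("WHO Asian BMI classes put boundaries in the upper class", {
  s <- define_strata(c(22.9, 23.0, 27.4, 27.5, 30))
  expect_identical(as.character(s),
                   c("normal", "overweight", "overweight", "obese", "obese"))
  expect_error(define_strata(1:5, cutpoints = c(2, 2)), "strictly increasing")
  expect_error(define_strata(c(1, NA)), "finite")
})

test_that("sex-specific tertiles are balanced and match a sort-based oracle", {
  set.seed(121)
  sex <- rep(c("M", "F"), each = 300)
  v <- c(runif(300, 70, 95), runif(300, 65, 90))
  s <- define_strata(v, sex, mode = "sex_specific_tertiles")
  for (sx in c("M", "F")) {
    expect_true(all(abs(table(s[sex == sx]) - 100) <= 1))
  }
  # 9-value hand set: sorted thirds
  v9 <- c(5, 9, 1, 7, 3, 8, 2, 6, 4)
  s9 <- define_strata(v9, rep("M", 9), mode = "sex_specific_tertiles")
  expect_identical(as.character(s9)[order(v9)],
                   rep(c("low", "medium", "high"), each = 3))
  expect_error(define_strata(rep(1, 10), rep("M", 10),
                             mode = "sex_specific_tertiles"), "constant")
})

test_that("stratified associations are homogeneous without interaction and monotone with it", {
  set.seed(122)
  n <- 30000
  score <- rnorm(n, 10, 2)
  bmi <- rnorm(n, 23.6, 3.4)
  strata <- define_strata(bmi)
  # no interaction
  y0 <- rbinom(n, 1, plogis(-3 + 0.15 * (score - 10)))
  st0 <- stratified_grs_association(score, y0, labels = strata)
  expect_true(all(abs(st0$beta - 0.15) < 3.5 * st0$se))
  # negative interaction: per-point effect declines with BMI
  eff <- 0.25 - 0.02 * (bmi - 23.6)
  y1 <- rbinom(n, 1, plogis(-3 + eff * (score - 10)))
  st1 <- stratified_grs_association(score, y1, labels = strata)
  expect_true(all(diff(st1$beta[match(c("normal", "overweight", "obese"),
                                      st1$stratum)]) < 0))
})

test_that("the interaction model recovers a known coefficient and its coding", {
  set.seed(123)
  n <- 50000
  score <- rnorm(n, 10, 2)
  bmi <- rnorm(n, 23.6, 3.4)
  eta <- -3 + 0.2 * (score - 10) + 0.08 * (bmi - 23.6) -
    0.02 * (score - 10) * (bmi - 23.6)
  y <- rbinom(n, 1, plogis(eta))
  r <- grs_interaction_test(score - 10, bmi - 23.6, y)
  expect_lt(abs(r$beta_interaction - (-0.02)), 3 * r$se_interaction)
  # the model matrix product column is the elementwise product
  mm <- model.matrix(~ grs * v, data.frame(grs = score[1:5], v = bmi[1:5]))
  expect_equal(unname(mm[, "grs:v"]), score[1:5] * bmi[1:5])
})

test_that("interaction p-values are uniform under the null", {
  set.seed(124)
  pv <- vapply(1:300, function(r) {
    n <- 400
    score <- rnorm(n); v <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.2 * score + 0.1 * v))
    grs_interaction_test(score, v, y)$p_interaction
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})

test_that("two-stratum saturated fits agree with the interaction coefficient", {
  set.seed(125)
  n <- 40000
  score <- rnorm(n)
  g <- rbinom(n, 1, 0.5)  # stratum indicator
  y <- rbinom(n, 1, plogis(-2 + 0.3 * score - 0.15 * score * g + 0.1 * g))
  st <- stratified_grs_association(score, y,
                                   labels = factor(g, labels = c("a", "b")))
  r <- grs_interaction_test(score, g, y)
  diff_strata <- st$beta[st$stratum == "b"] - st$beta[st$stratum == "a"]
  expect_equal(diff_strata, r$beta_interaction, tolerance = 1e-6)
})

test_that("GRS-trait slope matches the normal-equations oracle and recovers truth", {
  x10 <- c(8.1, 9.5, 10.2, 11.3, 9.9, 10.7, 8.8, 12.1, 10.0, 9.2)
  t10 <- c(24.1, 23.0, 23.9, 22.1, 23.3, 22.8, 24.5, 21.9, 23.1, 23.8)
  r <- grs_trait_association(x10, t10)
  expect_equal(r$slope, normal_eq_slope(t10, x10), tolerance = 1e-10)

  set.seed(126)
  n <- 20000
  score <- rnorm(n, 10, 2)
  trait <- 23.6 - 0.05 * score + rnorm(n, 0, 3)
  r2 <- grs_trait_association(score, trait)
  expect_lt(abs(r2$slope - (-0.05)), 3 * r2$se)
  # independence gives a near-zero slope
  r3 <- grs_trait_association(score, rnorm(n, 23.6, 3))
  expect_lt(abs(r3$slope), 3.5 * r3$se)
  expect_error(grs_trait_association(score, rep(1, n)), "zero variance")
})

test_that("stratifying on a mediator can fabricate heterogeneity (collider caution)", {
  # the GRS lowers adiposity and raises disease risk, adiposity itself
  # raises risk, and there is NO score-by-adiposity product in the
  # generating model; stratifying on the mediator nevertheless produces
  # apparent between-stratum heterogeneity of the per-point effect
  set.seed(127)
  reps <- 30
  res <- t(vapply(seq_len(reps), function(r) {
    n <- 12000
    score <- rnorm(n, 10, 2)
    bmi <- 23.6 - 1.0 * (score - 10) + rnorm(n, 0, 2)
    y <- rbinom(n, 1, plogis(-2.5 + 0.15 * (score - 10) +
                               0.25 * (bmi - 23.6)))
    strata <- define_strata(bmi, rep("M", n), mode = "sex_specific_tertiles")
    st <- stratified_grs_association(score, y, labels = strata)
    c(st$beta[match(c("low", "medium", "high"), st$stratum)],
      cochran_q(st$beta, st$se)$p_het)
  }, numeric(4)))
  # heterogeneity across strata is detected far above the nominal 5% rate
  expect_gt(mean(res[, 4] < 0.05), 0.2)
  # and the pattern is systematic: the middle stratum's estimate differs
  # from the outer strata
  expect_gt(mean(res[, 2]), mean(res[, 1]))
  expect_gt(mean(res[, 2]), mean(res[, 3]))
})
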