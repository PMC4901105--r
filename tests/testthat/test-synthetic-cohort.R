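test_that("genotype simulation respects degenerate and intermediate frequencies", {
  s0 <- snp_spec("fix0", raf = 0)
  s1 <- snp_spec("fix1", raf = 1)
  G <- simulate_genotypes(list(s0, s1), 500, seed = 11)
  expect_true(all(G[, "fix0"] == 0))
  expect_true(all(G[, "fix1"] == 2))

  s <- snp_spec("half", raf = 0.5)
  G <- simulate_genotypes(list(s), 10000, seed = 12)
  # exact binomial 99% interval for the allele count at raf = 0.5
  iv <- qbinom(c(0.005, 0.995), 2 * 10000, 0.5) / 10000
  expect_gte(mean(G), iv[1])
  expect_lte(mean(G), iv[2])
  counts <- table(factor(G, levels = 0:2))
  expect_gt(hwe_chi2_test(counts[[3]], counts[[2]], counts[[1]])$p, 0.001)
})

test_that("invalid SNP specifications are rejected", {
  expect_error(snp_spec("bad", raf = 1.2), "raf")
  expect_error(snp_spec("bad", raf = 0.5, missing_rate = 1), "missing_rate")
  expect_error(sim_config(target_prevalence = 0), "target_prevalence")
})

test_that("missingness is independent of genotype and at the stated rate", {
  s <- snp_spec("m", raf = 0.4, missing_rate = 0.2)
  G <- simulate_genotypes(list(s), 20000, seed = 13)
  expect_gt(mean(is.na(G)), 0.18); expect_lt(mean(is.na(G)), 0.22)
  # observed dosage mean unchanged by masking
  expect_lt(abs(mean(G, na.rm = TRUE) - 0.8), 3 * sqrt(0.4 * 0.6 / 2 / 16000) * 2)
})

test_that("phenotype simulation hits the target prevalence", {
  cfg <- sim_config(n_individuals = 20000,
                    snps = lapply(1:5, function(i)
                      snp_spec(paste0("s", i), 0.3, beta_true = 0)),
                    target_prevalence = 0.076, seed = 21)
  sim <- simulate_cohort(cfg)
  prev <- mean(sim$cohort$y)
  iv <- qbinom(c(0.005, 0.995), 20000, 0.076) / 20000
  expect_gte(prev, iv[1]); expect_lte(prev, iv[2])
  # latent severity is consistent with status by construction
  expect_true(all((sim$cohort$severity > 0) == (sim$cohort$y == 1)))
})

test_that("a single simulated effect is recovered by logistic refit", {
  cfg <- sim_config(n_individuals = 50000,
                    snps = list(snp_spec("s1", 0.4, beta_true = log(1.2))),
                    target_prevalence = 0.076,
                    beta_age = 0, beta_female = 0, beta_bmi = 0,
                    centre_sd = 0, seed = 22)
  sim <- simulate_cohort(cfg)
  ok <- !is.na(sim$genotypes[, 1])
  fit <- fit_snp_logistic(sim$genotypes[ok, 1], sim$cohort$y[ok])
  expect_gt(fit$ci_high, 1.2)
  expect_lt(fit$ci_low, 1.2)
})

test_that("allele frequency estimates converge to the specified raf", {
  rafs <- c(0.05, 0.2, 0.5, 0.8)
  G <- simulate_genotypes(lapply(seq_along(rafs), function(i)
    snp_spec(paste0("s", i), rafs[i])), 20000, seed = 23)
  est <- colMeans(G) / 2
  expect_true(all(abs(est - rafs) < 3 * sqrt(rafs * (1 - rafs) / (2 * 20000))))
})

test_that("winner's-curse selection matches the truncated-normal oracle", {
  # calibrate sample size so the z-statistic has mean ~4, then select at
  # the two-sided 5e-8 threshold (|z| > 5.45)
  raf <- 0.5
  des <- discovery_design(4000, 4000, alpha_select = 5e-8)
  pilot <- simulate_discovery(list(snp_spec("s", raf, beta_true = 0.05)),
                              des, reps = 50, seed = 31)
  se0 <- mean(pilot$se_hat)
  beta <- 4 * se0
  reps <- 4000
  d <- simulate_discovery(list(snp_spec("s", raf, beta_true = beta)),
                          des, reps = reps, seed = 32)
  thr <- qnorm(1 - 2.5e-8)
  expect_true(all(abs(d$beta_hat / d$se_hat)[d$selected] >= thr * 0.999))
  zsel <- (d$beta_hat / d$se_hat)[d$selected & d$beta_hat > 0]
  expect_gt(length(zsel), 50)
  oracle <- truncnorm_mean(4, thr)
  mc_se <- sd(zsel) / sqrt(length(zsel))
  expect_lt(abs(mean(zsel) - oracle), 3 * mc_se + 0.05)
})

test_that("null-effect discovery only selects beyond the z threshold", {
  des <- discovery_design(500, 500, alpha_select = 0.01)
  d <- simulate_discovery(list(snp_spec("s", 0.3, beta_true = 0)), des,
                          reps = 300, seed = 33)
  z <- abs(d$beta_hat / d$se_hat)
  expect_true(all(z[d$selected] >= qnorm(0.995) * 0.999))
  expect_true(all(z[!d$selected] <= qnorm(0.995) * 1.001))
})

test_that("full-power selection is unbiased", {
  des <- discovery_design(20000, 20000, alpha_select = 5e-8)
  d <- simulate_discovery(list(snp_spec("s", 0.5, beta_true = log(1.5))),
                          des, reps = 100, seed = 34)
  expect_true(all(d$selected))
  expect_lt(abs(mean(d$beta_hat) - log(1.5)), 3 * sd(d$beta_hat) / 10)
})

test_that("spectrum-bias subsetting restricts to severe cases and inflates effects", {
  cfg <- sim_config(n_individuals = 30000,
                    snps = list(snp_spec("s1", 0.4, beta_true = log(1.3))),
                    target_prevalence = 0.2,
                    beta_age = 0, beta_female = 0, beta_bmi = 0,
                    centre_sd = 0, seed = 41)
  sim <- simulate_cohort(cfg)
  full <- discovery_design(10, 10, case_severity_quantile = 0)
  expect_identical(simulate_spectrum_bias(sim$cohort, full),
                   seq_len(nrow(sim$cohort)))

  G <- sim$genotypes_complete[, 1]
  y <- sim$cohort$y
  beta_pop <- fit_snp_logistic(G, y)$beta
  reps <- 25
  res <- vapply(seq_len(reps), function(r) {
    cfg2 <- cfg; cfg2$seed <- 100 + r
    s <- simulate_cohort(cfg2)
    des <- discovery_design(10, 10, case_severity_quantile = 0.5)
    idx <- simulate_spectrum_bias(s$cohort, des)
    b_sub <- fit_snp_logistic(s$genotypes_complete[idx, 1], s$cohort$y[idx])$beta
    des2 <- discovery_design(10, 10, case_severity_quantile = 0.5,
                             control_hypernormal = TRUE)
    idx2 <- simulate_spectrum_bias(s$cohort, des2)
    b_hyp <- fit_snp_logistic(s$genotypes_complete[idx2, 1], s$cohort$y[idx2])$beta
    b_pop <- fit_snp_logistic(s$genotypes_complete[, 1], s$cohort$y)$beta
    c(b_pop, b_sub, b_hyp)
  }, numeric(3))
  expect_gt(mean(abs(res[2, ])), mean(abs(res[1, ])))   # case restriction inflates
  expect_gte(mean(abs(res[3, ])), mean(abs(res[2, ])))  # hyper-normal controls inflate further
})

test_that("null association p-values are uniform across many SNPs", {
  set.seed(51)
  n <- 5000; p <- 1000
  G <- matrix(rbinom(n * p, 2, 0.3), n, p)
  y <- rbinom(n, 1, 0.076)
  z <- t2dgrs:::score_z(G, y)
  pv <- 2 * pnorm(-abs(z))
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})
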