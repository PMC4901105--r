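#' Per-SNP simulation specification
#'
#' @param snp_id SNP identifier.
#' @param raf Risk-allele frequency in `[0, 1]`.
#' @param beta_true True per-allele log-OR for disease.
#' @param mechanism One of `"BC"`, `"IR"`, `"other"` (ground-truth mechanism
#'   label carried through to recovery tests).
#' @param missing_rate Probability that a genotype call is missing,
#'   independent of the genotype; must be `< 1`.
#' @return An object of class `snp_spec`.
#' @export
snp_spec <- function(snp_id, raf, beta_true = 0, mechanism = "other",
                     missing_rate = 0) {
  stopifnot(is.character(snp_id), length(snp_id) == 1L)
  if (!is.finite(raf) || raf < 0 || raf > 1)
    stop("raf must be in [0, 1] for ", snp_id)
  if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1) for ", snp_id)
  mechanism <- match.arg(mechanism, c("BC", "IR", "other"))
  structure(list(snp_id = snp_id, raf = raf, beta_true = beta_true,
                 mechanism = mechanism, missing_rate = missing_rate),
            class = "snp_spec")
}

#' Simulation configuration for the synthetic cohort
#'
#' Defaults emulate the baseline characteristics of the Chinese
#' population-based cohort the pipeline was designed around: ten regional
#' centres, 7.6% diabetes prevalence, 40.5% men, age 51.4 (SD 10.7) years,
#' and sex-specific adiposity distributions (BMI men 23.4 (3.2), women
#' 23.8 (3.5) kg/m^2; WC 82.0 (9.7) / 79.1 (9.6) cm; WHR 0.90 (0.06) /
#' 0.87 (0.07); PBF 21.9 (6.2) / 32.1 (7.2) %).  Adiposity measures are
#' drawn jointly with a fixed realistic correlation structure.  The default
#' SNP panel is [default_snp_panel()].
#'
#' @param n_individuals Cohort size.  The emulated cohort has 93,131
#'   genotyped participants; analyses and tests routinely pass smaller sizes.
#' @param n_centres Number of regional centres (>= 1).
#' @param snps List of [snp_spec()] objects.
#' @param target_prevalence Target disease prevalence in (0, 1).
#' @param age_mean,age_sd Age distribution (years), truncated to 30-79.
#' @param prop_male Proportion of men.
#' @param beta_age Log-OR per year of age.
#' @param beta_female Log-OR for women vs men.
#' @param beta_bmi Log-OR per kg/m^2 of BMI.
#' @param centre_sd SD of centre-level log-odds effects.
#' @param interaction_coef Change in each SNP's per-allele log-OR per unit of
#'   centred BMI (gene-adiposity interaction); 0 disables interaction.
#' @param seed Integer seed; all draws flow from this single stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 93131,
                       n_centres = 10,
                       snps = default_snp_panel(),
                       target_prevalence = 0.076,
                       age_mean = 51.4, age_sd = 10.7,
                       prop_male = 0.405,
                       beta_age = 0.05,
                       beta_female = 0.10,
                       beta_bmi = 0.10,
                       centre_sd = 0.15,
                       interaction_coef = 0,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_centres >= 1)
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must be in (0, 1)")
  stopifnot(all(vapply(snps, inherits, logical(1), "snp_spec")))
  structure(list(n_individuals = as.integer(n_individuals),
                 n_centres = as.integer(n_centres), snps = snps,
                 target_prevalence = target_prevalence,
                 age_mean = age_mean, age_sd = age_sd,
                 prop_male = prop_male, beta_age = beta_age,
                 beta_female = beta_female, beta_bmi = beta_bmi,
                 centre_sd = centre_sd, interaction_coef = interaction_coef,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype dosage matrix under Hardy-Weinberg proportions
#'
#' Dosages count copies of the risk allele, drawn as Binomial(2, raf) per
#' individual, independently across SNPs (no linkage disequilibrium).
#' Missingness is applied independently of genotype at each SNP's
#' `missing_rate`.
#'
#' @param snps List of [snp_spec()] objects.
#' @param n Number of individuals (>= 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Integer matrix `n x length(snps)` with entries 0/1/2 and `NA` for
#'   missing calls; rownames are individual ids, colnames SNP ids.
#' @export
simulate_genotypes <- function(snps, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(vapply(snps, inherits, logical(1), "snp_spec")))
  G <- vapply(snps, function(s) {
    g <- stats::rbinom(n, 2L, s$raf)
    if (s$missing_rate > 0)
      g[stats::runif(n) < s$missing_rate] <- NA_integer_
    g
  }, integer(n))
  if (n == 1L) G <- matrix(G, nrow = 1L)
  dimnames(G) <- list(sprintf("id_%06d", seq_len(n)),
                      vapply(snps, `[[`, character(1), "snp_id"))
  G
}

# Solve the disease-model intercept by bisection so that the expected
# prevalence over the simulated individuals hits the target (tolerance in
# prevalence units).
solve_intercept <- function(eta, target, tol = 1e-4) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence target unattainable")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) return(mid)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Correlated sex-specific adiposity draws (BMI, WC, WHR, PBF).
adiposity_params <- function() {
  corr <- matrix(c(1.00, 0.80, 0.45, 0.75,
                   0.80, 1.00, 0.70, 0.70,
                   0.45, 0.70, 1.00, 0.45,
                   0.75, 0.70, 0.45, 1.00), 4, 4,
                 dimnames = rep(list(c("bmi", "wc", "whr", "pbf")), 2))
  list(corr = corr,
       male   = list(mean = c(bmi = 23.4, wc = 82.0, whr = 0.90, pbf = 21.9),
                     sd   = c(bmi = 3.2,  wc = 9.7,  whr = 0.06, pbf = 6.2)),
       female = list(mean = c(bmi = 23.8, wc = 79.1, whr = 0.87, pbf = 32.1),
                     sd   = c(bmi = 3.5,  wc = 9.6,  whr = 0.07, pbf = 7.2)))
}

simulate_covariates <- function(config) {
  n <- config$n_individuals
  sex <- ifelse(stats::runif(n) < config$prop_male, "M", "F")
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  age <- pmin(pmax(age, 30), 79)
  centre <- factor(sample(sprintf("centre_%02d", seq_len(config$n_centres)),
                          n, replace = TRUE))
  ap <- adiposity_params()
  adi <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("bmi", "wc", "whr", "pbf")))
  for (s in c("M", "F")) {
    idx <- which(sex == s)
    par <- if (s == "M") ap$male else ap$female
    sig <- diag(par$sd) %*% ap$corr %*% diag(par$sd)
    adi[idx, ] <- MASS::mvrnorm(length(idx), par$mean, sig)
  }
  data.frame(id = sprintf("id_%06d", seq_len(n)), sex = sex, age = age,
             centre = centre, adi, stringsAsFactors = FALSE)
}

#' Simulate case/control status from genotypes under a logistic disease model
#'
#' The linear predictor combines per-allele genetic effects, age, sex, BMI
#' and centre effects, plus an optional gene-adiposity interaction in which
#' each SNP's log-OR changes by `interaction_coef` per unit of centred BMI.
#' The intercept is solved by bisection so the expected prevalence over the
#' simulated covariate distribution matches `target_prevalence` to 1e-4.
#' Disease status is generated through an explicit latent liability
#' (`severity = intercept + eta + logistic noise`; case iff `severity > 0`),
#' which downstream spectrum-bias sampling reuses.
#'
#' @param G Complete dosage matrix (no missing values), row-aligned with
#'   `covariates`.
#' @param config A [sim_config()].
#' @param covariates Data frame from the internal covariate simulator; drawn
#'   fresh when `NULL`.
#' @return List with `y` (0/1), `severity` (latent liability), `intercept`,
#'   and `covariates`.
#' @export
simulate_phenotype <- function(G, config, covariates = NULL) {
  if (is.null(covariates)) covariates <- simulate_covariates(config)
  stopifnot(nrow(G) == nrow(covariates))
  if (anyNA(G)) stop("G must be complete (apply missingness after phenotype)")
  beta <- vapply(config$snps, `[[`, numeric(1), "beta_true")
  bmi_c <- covariates$bmi - mean(covariates$bmi)
  eta_g <- drop(G %*% beta)
  if (config$interaction_coef != 0)
    eta_g <- eta_g + config$interaction_coef * bmi_c * rowSums(G)
  centre_eff <- stats::rnorm(config$n_centres, 0, config$centre_sd)
  eta <- eta_g +
    config$beta_age * (covariates$age - config$age_mean) +
    config$beta_female * (covariates$sex == "F") +
    config$beta_bmi * bmi_c +
    centre_eff[as.integer(covariates$centre)]
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  intercept <- solve_intercept(eta, config$target_prevalence)
  severity <- intercept + eta + stats::rlogis(length(eta))
  list(y = as.integer(severity > 0), severity = severity,
       intercept = intercept, covariates = covariates)
}

#' Simulate a full cohort with known ground truth
#'
#' Convenience wrapper: draws covariates, complete genotypes, phenotype and
#' latent severity from `config$seed`, then masks genotypes at each SNP's
#' `missing_rate`.  Screening fields (self-report, random/fasting glucose,
#' fasting time) are generated so the diabetes-classification rules have
#' realistic inputs: roughly 40% of cases self-report, the remainder carry
#' elevated glucose.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (with missingness), `genotypes_complete`,
#'   `cohort` (covariates + `y` + `severity` + screening fields), `truth`
#'   (snp_id, raf, beta_true, mechanism), `intercept` and `seed`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  covariates <- simulate_covariates(config)
  specs_complete <- lapply(config$snps, function(s) {
    s$missing_rate <- 0; s
  })
  G <- simulate_genotypes(specs_complete, config$n_individuals, seed = NULL)
  ph <- simulate_phenotype(G, config, covariates)
  Gobs <- G
  for (j in seq_along(config$snps)) {
    mr <- config$snps[[j]]$missing_rate
    if (mr > 0)
      Gobs[stats::runif(nrow(G)) < mr, j] <- NA_integer_
  }
  n <- config$n_individuals
  y <- ph$y
  self_report <- y == 1L & stats::runif(n) < 0.4
  random_glucose <- ifelse(y == 1L,
                           pmax(stats::rnorm(n, 9.5, 2.5), 7.0),
                           pmin(pmax(stats::rnorm(n, 6.0, 1.0), 3.0), 6.9))
  fasting_time <- stats::rexp(n, 1 / 6)
  cohort <- cbind(ph$covariates,
                  data.frame(y = y, severity = ph$severity,
                             self_report_diabetes = self_report,
                             age_at_onset = ifelse(self_report,
                                                   ph$covariates$age -
                                                     stats::rexp(n, 1 / 5), NA),
                             insulin_treated = self_report & stats::runif(n) < 0.1,
                             random_glucose = random_glucose,
                             fasting_time = fasting_time))
  truth <- data.frame(
    snp_id = vapply(config$snps, `[[`, character(1), "snp_id"),
    raf = vapply(config$snps, `[[`, numeric(1), "raf"),
    beta_true = vapply(config$snps, `[[`, numeric(1), "beta_true"),
    mechanism = vapply(config$snps, `[[`, character(1), "mechanism"),
    stringsAsFactors = FALSE)
  list(genotypes = Gobs, genotypes_complete = G, cohort = cohort,
       truth = truth, intercept = ph$intercept, seed = config$seed)
}

#' Discovery-study design for winner's-curse / spectrum-bias simulation
#'
#' @param n_cases,n_controls Case and control counts per replicate.
#' @param alpha_select Significance threshold a replicate must pass to be
#'   "discovered" (GWAS convention 5e-8).
#' @param case_severity_quantile Fraction of least-severe cases dropped by
#'   spectrum-bias sampling (0 keeps all cases).
#' @param control_hypernormal If `TRUE`, controls are restricted to the
#'   low-liability half ("hyper-normal" controls).
#' @return An object of class `discovery_design`.
#' @export
discovery_design <- function(n_cases, n_controls, alpha_select = 5e-8,
                             case_severity_quantile = 0,
                             control_hypernormal = FALSE) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  if (alpha_select <= 0 || alpha_select >= 1)
    stop("alpha_select must be in (0, 1)")
  stopifnot(case_severity_quantile >= 0, case_severity_quantile <= 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 alpha_select = alpha_select,
                 case_severity_quantile = case_severity_quantile,
                 control_hypernormal = isTRUE(control_hypernormal)),
            class = "discovery_design")
}

#' Simulate discovery-study effect estimates with significance selection
#'
#' Each replicate draws a case-control study at a single SNP: control
#' genotypes follow Hardy-Weinberg proportions at the risk-allele frequency
#' and case genotype probabilities are proportional to
#' `HWE(g) * exp(beta_true * g)` (the logistic disease model under the
#' rare-disease approximation), then the per-allele log-OR and Wald SE are
#' estimated by logistic regression on the collapsed 2 x 3 table.  A
#' replicate is `selected` iff its Wald p < `alpha_select` -- the
#' winner's-curse mechanism.  All estimates are retained with flags.
#'
#' @param snps List of [snp_spec()] objects.
#' @param design A [discovery_design()].
#' @param reps Replicates per SNP (>= 1).
#' @param seed Optional integer seed.
#' @return Data frame (snp_id, rep, beta_true, beta_hat, se_hat, p, selected).
#' @export
simulate_discovery <- function(snps, design, reps = 1, seed = NULL) {
  stopifnot(reps >= 1, inherits(design, "discovery_design"))
  if (!is.null(seed)) set.seed(seed)
  if (design$n_cases < 1 || design$n_controls < 1)
    stop("need at least one case and one control")
  out <- lapply(snps, function(s) {
    p0 <- c((1 - s$raf)^2, 2 * s$raf * (1 - s$raf), s$raf^2)
    p1 <- p0 * exp(s$beta_true * 0:2)
    p1 <- p1 / sum(p1)
    res <- t(vapply(seq_len(reps), function(r) {
      ca <- drop(stats::rmultinom(1, design$n_cases, p1))
      co <- drop(stats::rmultinom(1, design$n_controls, p0))
      est <- logistic_from_counts(ca, co)
      c(est$beta, est$se, est$p)
    }, numeric(3)))
    data.frame(snp_id = s$snp_id, rep = seq_len(reps),
               beta_true = s$beta_true, beta_hat = res[, 1],
               se_hat = res[, 2], p = res[, 3],
               selected = res[, 3] < design$alpha_select,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-allele logistic fit on a collapsed dosage (0/1/2) x outcome table.
logistic_from_counts <- function(cases, controls) {
  df <- data.frame(g = 0:2, ca = cases, co = controls)
  df <- df[df$ca + df$co > 0, ]
  fit <- stats::glm(cbind(ca, co) ~ g, family = stats::binomial(), data = df)
  sm <- summary(fit)$coefficients
  if (!"g" %in% rownames(sm))
    return(list(beta = NA_real_, se = NA_real_, p = 1))
  list(beta = sm["g", 1], se = sm["g", 2],
       p = 2 * stats::pnorm(-abs(sm["g", 1] / sm["g", 2])))
}

#' Mean of a selected (truncated) normal effect estimate
#'
#' Closed-form oracle for the conditional mean of `Z ~ N(mu, 1)` given
#' `Z > c`: `mu + dnorm(c - mu) / (1 - pnorm(c - mu))`.  Used to check the
#' winner's-curse bias of selected discovery estimates.
#'
#' @param mu True mean of the z-statistic.
#' @param c Selection threshold on z.
#' @return Expected z given selection.
#' @export
truncnorm_mean <- function(mu, c) {
  mu + stats::dnorm(c - mu) / (1 - stats::pnorm(c - mu))
}

#' Restrict a cohort to a spectrum-biased subsample
#'
#' Emulates "clear-cut case" / "hyper-normal control" sampling: cases below
#' the `case_severity_quantile` quantile of case severity are dropped, and,
#' when `control_hypernormal` is set, controls are restricted to the
#' low-liability half.  Severity is the latent liability produced by
#' [simulate_phenotype()].
#'
#' @param cohort Cohort data frame with `y` and `severity` columns.
#' @param design A [discovery_design()].
#' @return Integer vector of retained row indices.
#' @export
simulate_spectrum_bias <- function(cohort, design) {
  stopifnot(all(c("y", "severity") %in% names(cohort)))
  case_idx <- which(cohort$y == 1L)
  ctrl_idx <- which(cohort$y == 0L)
  q <- design$case_severity_quantile
  if (q > 0) {
    cut <- stats::quantile(cohort$severity[case_idx], q, type = 7)
    case_idx <- case_idx[cohort$severity[case_idx] >= cut]
  }
  if (design$control_hypernormal) {
    cut <- stats::median(cohort$severity[ctrl_idx])
    ctrl_idx <- ctrl_idx[cohort$severity[ctrl_idx] <= cut]
  }
  if (length(case_idx) < 2 || length(ctrl_idx) < 2)
    stop("spectrum subset leaves fewer than 2 cases or 2 controls")
  sort(c(case_idx, ctrl_idx))
}
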