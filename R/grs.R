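#' Impute missing dosages by regional-centre mean genotype
#'
#' Each missing dosage is replaced by the mean observed dosage of that SNP
#' within the individual's regional centre; if a centre has no observed
#' calls for a SNP, the overall mean is used (with a warning).  A SNP with
#' no observed calls anywhere is an error.
#'
#' @param G Dosage matrix (0/1/2/NA), samples in rows.
#' @param centre Centre label per sample.
#' @return List with `G` (completed numeric matrix) and `n_imputed`
#'   (per-sample count of imputed genotypes).
#' @export
impute_missing_by_centre_mean <- function(G, centre) {
  stopifnot(length(centre) == nrow(G))
  centre <- as.factor(centre)
  out <- apply(G, 2, as.numeric)
  dimnames(out) <- dimnames(G)
  n_imputed <- integer(nrow(G))
  for (j in seq_len(ncol(out))) {
    miss <- is.na(out[, j])
    if (!any(miss)) next
    if (all(miss)) stop("SNP ", colnames(G)[j], " has no observed genotypes")
    overall <- mean(out[!miss, j])
    cm <- tapply(out[!miss, j], centre[!miss], mean)
    fill <- cm[as.character(centre[miss])]
    if (anyNA(fill)) {
      warning("centre with no observed calls for ", colnames(G)[j],
              "; falling back to overall mean")
      fill[is.na(fill)] <- overall
    }
    out[miss, j] <- fill
    n_imputed[miss] <- n_imputed[miss] + 1L
  }
  list(G = out, n_imputed = n_imputed)
}

#' Compute a (weighted) genetic risk score with rescaling
#'
#' Raw score: `sum(w_i * g_i)` over the SNPs of the definition.  The
#' rescaled score multiplies by
#' `total risk alleles / (2 * sum of weights) = (2 M) / (2 sum(w))`, where
#' `M` is the number of SNPs, so that one point of the rescaled score
#' corresponds on average to one additional risk allele; with equal unit
#' weights the rescaled score is exactly the risk-allele count.
#'
#' @param G Completed dosage matrix containing all SNPs of the score.
#' @param snp_ids SNPs included in the score.
#' @param weights Named numeric vector of per-SNP weights (natural-log
#'   per-allele ORs), or a single value recycled; `sum(weights)` must be
#'   positive.  Unweighted scores use weight 1 for every SNP.
#' @param n_imputed Optional per-sample imputation counts to carry through.
#' @return Data frame (`id`, `raw`, `rescaled`, `n_imputed`).
#' @export
compute_grs <- function(G, snp_ids, weights = 1, n_imputed = NULL) {
  missing_snps <- setdiff(snp_ids, colnames(G))
  if (length(missing_snps))
    stop("SNPs absent from genotype matrix: ",
         paste(missing_snps, collapse = ", "))
  if (length(weights) == 1) {
    weights <- stats::setNames(rep(weights, length(snp_ids)), snp_ids)
  }
  if (!all(snp_ids %in% names(weights)))
    stop("weights missing for some SNPs in the score")
  w <- weights[snp_ids]
  if (any(!is.finite(w))) stop("weights must be finite")
  if (sum(w) <= 0) stop("sum of weights must be positive")
  Gs <- G[, snp_ids, drop = FALSE]
  if (anyNA(Gs)) stop("genotypes must be completed (impute first)")
  raw <- drop(Gs %*% w)
  M <- length(snp_ids)
  rescaled <- raw * (2 * M) / (2 * sum(w))
  data.frame(id = if (is.null(rownames(G))) seq_len(nrow(G)) else rownames(G),
             raw = raw, rescaled = rescaled,
             n_imputed = if (is.null(n_imputed)) 0L else n_imputed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a risk variant's predominant mechanism from evidence flags
#'
#' A variant is beta-cell related (`BC`) if any beta-cell criterion holds:
#' decreased HOMA-B in non-diabetic individuals, a beta-cell function index
#' during an OGTT, membership of a beta-cell cluster, or a monogenic
#' insulin-secretion locus.  Otherwise it is insulin-resistance related
#' (`IR`) if any IR criterion holds (increased HOMA-IR / decreased insulin
#' sensitivity, raised fasting insulin, IR cluster membership, or
#' triacylglycerol/other IR traits) *and* it does not act primarily through
#' obesity; otherwise `unclassified`.  BC takes precedence when both lines
#' of evidence are present (the published classes are disjoint; the
#' tie-break is this package's rule and can be changed via `prefer`).
#'
#' @param evidence Data frame with logical columns `homa_b_decreased`,
#'   `ogtt_bc_index`, `bc_cluster`, `monogenic_locus`, `homa_ir_increased`,
#'   `fasting_insulin_up`, `ir_cluster`, `triacylglycerol_ir_trait`,
#'   `obesity_mediated` (absent columns count as all-FALSE).
#' @param prefer Class assigned when both BC and IR evidence is present.
#' @return Character vector of `"BC"`, `"IR"`, `"unclassified"`.
#' @export
classify_mechanism <- function(evidence, prefer = c("BC", "IR")) {
  prefer <- match.arg(prefer)
  get <- function(nm) {
    if (nm %in% names(evidence)) isTRUE_vec(evidence[[nm]])
    else rep(FALSE, nrow(evidence))
  }
  bc <- get("homa_b_decreased") | get("ogtt_bc_index") |
        get("bc_cluster") | get("monogenic_locus")
  ir <- (get("homa_ir_increased") | get("fasting_insulin_up") |
         get("ir_cluster") | get("triacylglycerol_ir_trait")) &
        !get("obesity_mediated")
  out <- rep("unclassified", nrow(evidence))
  if (prefer == "BC") {
    out[ir] <- "IR"; out[bc] <- "BC"
  } else {
    out[bc] <- "BC"; out[ir] <- "IR"
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Proportion of phenotype variance explained by a SNP
#'
#' Plug-in estimator from a reported effect size, its SE, the allele
#' frequency and the sample size:
#' `PVE = 2 b^2 p (1-p) / (2 b^2 p (1-p) + se^2 * 2 n * p (1-p))`.
#'
#' @param beta Reported per-allele effect.
#' @param se Its standard error (> 0).
#' @param raf Risk-allele frequency in (0, 1).
#' @param n Sample size (> 0).
#' @return PVE in `[0, 1]` (vectorised).
#' @export
variance_explained <- function(beta, se, raf, n) {
  if (any(se <= 0) || any(n <= 0)) stop("se and n must be positive")
  if (any(raf <= 0 | raf >= 1)) stop("raf must lie strictly in (0, 1)")
  num <- 2 * beta^2 * raf * (1 - raf)
  num / (num + se^2 * 2 * n * raf * (1 - raf))
}

# Floated (quasi-)variances for the levels of a categorical exposure:
# least-squares fit of f_i + f_j to all pairwise contrast variances
# c_ij = V_ii + V_jj - 2 V_ij (reference level included with zero rows/cols
# in V), weighted by 1/c_ij^2 (relative error).  Solved by the minimum-norm
# pseudoinverse so the 2-level case (one equation, two unknowns) gets the
# natural equal split, which reproduces the contrast variance exactly.
floated_variances <- function(V) {
  k <- nrow(V)
  pairs <- utils::combn(k, 2)
  cvar <- apply(pairs, 2, function(ij) {
    V[ij[1], ij[1]] + V[ij[2], ij[2]] - 2 * V[ij[1], ij[2]]
  })
  A <- matrix(0, ncol(pairs), k)
  for (m in seq_len(ncol(pairs))) A[m, pairs[, m]] <- 1
  sw <- 1 / cvar  # sqrt of the 1/c^2 weights
  f <- drop(MASS::ginv(A * sw) %*% (cvar * sw))
  stats::setNames(f, rownames(V))
}

#' GRS quartile association with floated absolute risks
#'
#' Forms quartiles of the score on the full sample (boundary ties assigned
#' to the lower quartile), fits a covariate-adjusted logistic model with
#' quartile indicators (lowest quartile = reference), and assigns a floated
#' variance to every level -- including the reference -- such that the
#' variance of any pairwise log-OR contrast is approximated by the sum of
#' the two floated variances (quasi-variance approach; exact for two
#' levels).  Each level's CI is `exp(est +- 1.959964 sqrt(float))`.
#'
#' @param score Numeric risk score (>= 4 distinct values).
#' @param y Binary outcome.
#' @param covariates Optional covariate data frame.
#' @param n_groups Number of score groups (default quartiles).
#' @return List with `table` (per-quartile `n_cases`, `n_controls`,
#'   `log_or`, `float_var`, `or_`, `ci_low`, `ci_high`) and `vcov` (the
#'   fitted covariance of the quartile log-ORs, reference row/col zero).
#' @export
quartile_association <- function(score, y, covariates = NULL, n_groups = 4) {
  if (length(unique(score)) < n_groups)
    stop("score needs at least ", n_groups, " distinct values")
  qs <- stats::quantile(score, probs = seq_len(n_groups - 1) / n_groups,
                        type = 7)
  grp <- factor(findInterval(score, qs, left.open = TRUE) + 1L,
                levels = seq_len(n_groups),
                labels = paste0("Q", seq_len(n_groups)))
  if (any(table(grp) == 0)) stop("empty score quartile")
  if (any(table(grp, y) == 0)) stop("quartile with a single outcome class")
  dat <- data.frame(y = y, grp = grp)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = dat)
  cn <- paste0("grp", levels(grp)[-1])
  est <- c(0, stats::coef(fit)[cn])
  Vfit <- stats::vcov(fit)[cn, cn, drop = FALSE]
  V <- matrix(0, n_groups, n_groups,
              dimnames = list(levels(grp), levels(grp)))
  V[-1, -1] <- Vfit
  fl <- floated_variances(V)
  zq <- 1.959964
  tab <- data.frame(quartile = levels(grp),
                    n_cases = as.integer(table(grp[y == 1])),
                    n_controls = as.integer(table(grp[y == 0])),
                    log_or = unname(est), float_var = unname(fl),
                    or_ = exp(unname(est)),
                    ci_low = exp(unname(est) - zq * sqrt(unname(fl))),
                    ci_high = exp(unname(est) + zq * sqrt(unname(fl))),
                    stringsAsFactors = FALSE)
  list(table = tab, vcov = V)
}
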