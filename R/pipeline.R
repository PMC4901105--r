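#' Write / read the genotype TSV dialect
#'
#' Rows are individuals, the first column is the individual id, remaining
#' columns are per-SNP risk-allele dosages with `NA` for missing calls.
#' The dialect is deliberately plain so test fixtures diff cleanly.
#'
#' @param G Dosage matrix.
#' @param path Output path.
#' @export
write_genotype_tsv <- function(G, path) {
  df <- data.frame(id = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @return `read_genotype_tsv`: the dosage matrix with individual ids as
#'   rownames.
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                          stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- df[[1]]
  G
}

strand_ambiguous <- function(a1, a2) {
  pair <- paste(pmin(a1, a2), pmax(a1, a2))
  pair %in% c("A T", "C G")
}

#' Read genotypes with risk-allele alignment
#'
#' Reads a dosage matrix from the package TSV dialect, a PLINK `.raw`
#' export, or a VCF (GT field only), and orients every dosage to count the
#' risk allele given in `snp_metadata`:
#' \itemize{
#'   \item TSV: dosages are taken as already risk-allele oriented.
#'   \item PLINK `.raw`: the counted allele is parsed from each `SNP_A`
#'     header; when it equals the alternative allele the dosage is flipped
#'     (`2 - x`); an allele matching neither is an error naming the SNP.
#'   \item VCF: GT alt-allele counts; records whose REF is the risk allele
#'     are flipped.
#' }
#' Strand-ambiguous (A/T, C/G) SNPs trigger a warning and are taken at face
#' value -- they are never strand-flipped.
#'
#' @param path Input file.
#' @param format `"tsv"`, `"plink_raw"` or `"vcf"`.
#' @param snp_metadata Data frame with `snp_id`, `risk_allele`,
#'   `alt_allele`.
#' @return Integer dosage matrix (individuals x SNPs), risk-allele counted.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_raw", "vcf"),
                           snp_metadata = NULL) {
  format <- match.arg(format)
  if (format == "tsv") return(read_genotype_tsv(path))
  stopifnot(!is.null(snp_metadata),
            all(c("snp_id", "risk_allele", "alt_allele") %in%
                  names(snp_metadata)))
  if (any(strand_ambiguous(snp_metadata$risk_allele,
                           snp_metadata$alt_allele)))
    warning("strand-ambiguous (A/T or C/G) SNPs present: ",
            paste(snp_metadata$snp_id[
              strand_ambiguous(snp_metadata$risk_allele,
                               snp_metadata$alt_allele)], collapse = ", "),
            "; dosages taken at face value, never strand-flipped")
  if (format == "plink_raw") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    meta_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                           names(df))
    snp_cols <- setdiff(names(df), meta_cols)
    ids <- sub("_[^_]+$", "", snp_cols)
    counted <- sub("^.*_", "", snp_cols)
    G <- as.matrix(df[, snp_cols, drop = FALSE])
    storage.mode(G) <- "integer"
    colnames(G) <- ids
    rownames(G) <- if ("IID" %in% names(df)) df$IID else seq_len(nrow(df))
    for (j in seq_along(ids)) {
      m <- snp_metadata[snp_metadata$snp_id == ids[j], ]
      if (nrow(m) == 0) stop("no metadata for SNP ", ids[j])
      if (counted[j] == m$risk_allele) next
      if (counted[j] == m$alt_allele) G[, j] <- 2L - G[, j]
      else stop("counted allele ", counted[j], " for ", ids[j],
                " matches neither risk nor alternative allele")
    }
    return(G)
  }
  # VCF, GT field only
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- apply(gt, 2, function(col) {
    vapply(strsplit(gsub("\\|", "/", col), "/"), function(a) {
      if (length(a) == 0 || any(a == ".")) NA_integer_
      else sum(as.integer(a) > 0)
    }, integer(1))
  })
  if (is.null(dim(alt_count)))
    alt_count <- matrix(alt_count, nrow = nrow(gt),
                        dimnames = dimnames(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  G <- t(alt_count)
  colnames(G) <- fix$ID
  storage.mode(G) <- "integer"
  for (j in seq_len(ncol(G))) {
    m <- snp_metadata[snp_metadata$snp_id == fix$ID[j], ]
    if (nrow(m) == 0) stop("no metadata for SNP ", fix$ID[j])
    if (fix$ALT[j] == m$risk_allele && fix$REF[j] == m$alt_allele) next
    if (fix$REF[j] == m$risk_allele && fix$ALT[j] == m$alt_allele)
      G[, j] <- 2L - G[, j]
    else stop("VCF alleles ", fix$REF[j], "/", fix$ALT[j], " for ",
              fix$ID[j], " cannot be reconciled with metadata")
  }
  G
}

write_stage_tsv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full analysis pipeline on a simulated or supplied cohort
#'
#' Orchestrates the stages end to end: cohort simulation (or file input),
#' SNP and sample QC, per-SNP covariate-adjusted association, meta-analysis
#' against external summary statistics, winner's-curse attenuation
#' (through-origin WLS of cohort on external log-ORs), centre-mean
#' imputation and GRS construction (overall and, when mechanism labels are
#' available, beta-cell and insulin-resistance subscores), ROC
#' discrimination of unweighted vs weighted scores, and BMI-stratified
#' association with the GRS-by-BMI interaction test.  Every stage writes a
#' TSV under `output_dir`, and a manifest with MD5 checksums and the seed
#' records the run; identical config and seed give identical outputs.
#'
#' @param config List with either `simulation` (a [sim_config()]) or
#'   `genotypes` + `cohort` (paths or objects), optional `external`
#'   summary-statistic data frame (`snp_id`, `beta`, `se`), QC thresholds
#'   (`snp_call_threshold`, `hwe_threshold`, `sample_call_threshold`,
#'   `f_zscore_threshold`), and `output_dir`.
#' @return The run manifest (data frame of files with checksums),
#'   invisibly; stage results are attached as the `"results"` attribute.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$output_dir %||% tempfile("t2dgrs_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$simulation)) {
    sim <- simulate_cohort(config$simulation)
    G <- sim$genotypes
    cohort <- sim$cohort
    truth <- sim$truth
    seed <- config$simulation$seed
  } else {
    G <- if (is.character(config$genotypes)) read_genotype_tsv(config$genotypes)
         else config$genotypes
    cohort <- if (is.character(config$cohort))
      utils::read.delim(config$cohort, stringsAsFactors = FALSE)
      else config$cohort
    truth <- NULL
    seed <- config$seed %||% NA_integer_
  }
  results <- list()
  files <- character()

  # -- QC ---------------------------------------------------------------
  sq <- snp_qc(G, config$snp_call_threshold %||% 0.95,
               config$hwe_threshold %||% 1.3e-4)
  samq <- sample_qc(G, config$sample_call_threshold %||% 0.98,
                    config$f_zscore_threshold %||% 5)
  keep_snp <- sq$kept & !sq$monomorphic
  G <- G[samq$kept, keep_snp, drop = FALSE]
  cohort <- cohort[samq$kept, , drop = FALSE]
  results$snp_qc <- sq; results$sample_qc <- samq
  files <- c(files, write_stage_tsv(sq, out_dir, "snp_qc"),
             write_stage_tsv(samq, out_dir, "sample_qc"))
  message(sprintf("qc: %d/%d SNPs, %d/%d samples kept",
                  sum(keep_snp), nrow(sq), sum(samq$kept), nrow(samq)))

  covars <- cohort[, intersect(c("age", "sex", "centre"), names(cohort)),
                   drop = FALSE]
  if ("centre" %in% names(covars)) covars$centre <- factor(covars$centre)
  y <- cohort$y

  # -- association ------------------------------------------------------
  assoc <- assoc_scan(G, y, covars)
  assoc$p_holm <- adjust_pvalues(assoc$p, "holm")
  assoc$p_bh <- adjust_pvalues(assoc$p, "bh")
  results$association <- assoc
  files <- c(files, write_stage_tsv(assoc, out_dir, "association"))

  # -- meta-analysis + shrinkage vs external estimates ------------------
  ext <- config$external
  if (!is.null(ext)) {
    shared <- intersect(assoc$snp_id, ext$snp_id)
    a <- assoc[match(shared, assoc$snp_id), ]
    e <- ext[match(shared, ext$snp_id), ]
    meta <- do.call(rbind, lapply(seq_along(shared), function(i) {
      ivw_fixed_meta(c(a$beta[i], e$beta[i]), c(a$se[i], e$se[i]),
                     snp_id = shared[i])
    }))
    shr <- through_origin_wls(e$beta, a$beta, a$se)
    nz <- a$beta != 0 & e$beta != 0
    conc <- sign_concordance_test(sign(a$beta[nz]), sign(e$beta[nz]))
    results$meta <- meta; results$shrinkage <- shr
    results$concordance <- conc
    files <- c(files, write_stage_tsv(meta, out_dir, "meta"),
               write_stage_tsv(shr, out_dir, "shrinkage"))
  }

  # -- GRS --------------------------------------------------------------
  imp <- impute_missing_by_centre_mean(G, cohort$centre)
  grs_u <- compute_grs(imp$G, colnames(G), 1, imp$n_imputed)
  wts <- if (!is.null(ext)) {
    stats::setNames(ext$beta[match(colnames(G), ext$snp_id)], colnames(G))
  } else stats::setNames(assoc$beta, assoc$snp_id)
  wts[!is.finite(wts) | wts <= 0] <- 1e-6  # guard degenerate weights
  grs_w <- compute_grs(imp$G, colnames(G), wts, imp$n_imputed)
  results$grs <- data.frame(id = grs_u$id, unweighted = grs_u$rescaled,
                            weighted = grs_w$rescaled,
                            n_imputed = grs_u$n_imputed)
  files <- c(files, write_stage_tsv(results$grs, out_dir, "grs"))
  quart <- quartile_association(grs_w$rescaled, y, covars)
  results$grs_quartiles <- quart$table
  files <- c(files, write_stage_tsv(quart$table, out_dir, "grs_quartiles"))

  # -- discrimination ---------------------------------------------------
  roc_u <- c_statistic(grs_u$rescaled, y)
  roc_w <- c_statistic(grs_w$rescaled, y)
  dl <- delong_test(grs_w$rescaled, grs_u$rescaled, y)
  results$discrimination <- cbind(
    data.frame(score = c("unweighted", "weighted")),
    rbind(roc_u, roc_w))
  results$delong <- dl
  files <- c(files, write_stage_tsv(results$discrimination, out_dir, "roc"),
             write_stage_tsv(dl, out_dir, "delong"))

  # -- strata / interaction ---------------------------------------------
  if ("bmi" %in% names(cohort)) {
    strata <- define_strata(cohort$bmi)
    st <- stratified_grs_association(grs_w$rescaled, y, covars, strata)
    it <- grs_interaction_test(grs_w$rescaled, cohort$bmi, y, covars)
    st$p_interaction <- it$p_interaction
    results$strata <- st; results$interaction <- it
    files <- c(files, write_stage_tsv(st, out_dir, "strata"),
               write_stage_tsv(it, out_dir, "interaction"))
  }
  if (!is.null(truth))
    files <- c(files, write_stage_tsv(truth, out_dir, "truth"))

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  attr(manifest, "results") <- results
  attr(manifest, "output_dir") <- out_dir
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
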