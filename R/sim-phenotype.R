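# Phenotype construction and marginal-regression GWAS summary statistics.

#' Simulate a phenotype and its GWAS summary statistics
#'
#' The phenotype is the sum of (i) an expression-mediated genetic component
#' `sum_g alpha_g * (X_std %*% bbar_g)`, (ii) direct SNP effects, (iii)
#' covariate effects (age-like and sex-like columns with fixed small effects
#' of 0.1 on the standardized scale), and (iv) Gaussian noise filling the
#' covariate-adjusted variance to 1. Summary statistics are per-SNP marginal
#' OLS z-statistics of the covariate-residualized phenotype on each dosage,
#' with the effect allele `a1` matching the dosage coding.
#'
#' @param genotypes Cohort genotypes (drawn independently of the reference
#'   panel).
#' @param truth An `xtwas_truth` object.
#' @param config An [sim_config()] object.
#' @return List with `phenotype` (numeric vector), `covariates` (matrix,
#'   possibly 0 columns), `gwas` (a `data.table` with
#'   `snp, chr, pos, a1, a2, z, n, p`), and `mediated` (the latent mediated
#'   component, for variance-decomposition checks).
#' @export
simulate_phenotype_and_gwas <- function(genotypes, truth, config) {
  n <- nrow(genotypes$X)
  sp <- genotypes$snps
  Xs <- standardize_columns(genotypes$X)$X
  mediated <- rep(0, n)
  for (gi in seq_along(truth$genes)) {
    idx <- which(sp$gene_id == truth$genes[gi])
    mediated <- mediated + truth$alpha[gi] *
      (Xs[, idx, drop = FALSE] %*% rowMeans(truth$effects[[gi]]))[, 1]
  }
  direct <- as.vector(Xs %*% truth$direct)
  covars <- make_covariates(n, config$n_covariates)
  cov_eff <- if (ncol(covars) > 0) {
    as.vector(covars %*% rep(0.1, ncol(covars)))
  } else 0
  resid_var <- 1 - config$mediated_h2 - config$direct_h2
  assert_that(resid_var > 0, "variance targets infeasible")
  y <- mediated + direct + cov_eff + rnorm(n, sd = sqrt(resid_var))
  z <- marginal_z(genotypes$X, residualize(y, covars))
  gwas <- data.table::data.table(
    snp = sp$snp, chr = sp$chr, pos = sp$pos, a1 = sp$a1, a2 = sp$a2,
    z = z, n = n, p = 2 * pnorm(-abs(z)))
  list(phenotype = y, covariates = covars, gwas = gwas, mediated = mediated)
}

#' @noRd
make_covariates <- function(n, n_covariates) {
  if (n_covariates == 0L) return(matrix(0, n, 0))
  cols <- list(age = rnorm(n))
  if (n_covariates >= 2L) cols$sex <- rbinom(n, 1L, 0.5)
  if (n_covariates > 2L) {
    for (k in 3:n_covariates) cols[[paste0("cov", k)]] <- rnorm(n)
  }
  do.call(cbind, cols[seq_len(n_covariates)])
}

#' Simulate a complete study
#'
#' Orchestrates the generator: annotation, reference-panel genotypes and
#' multi-tissue expression, truth (causal architecture), and disjoint GWAS,
#' training and testing cohorts that share the SNP map but are drawn
#' independently. Everything downstream of [sim_config()] is reproducible
#' from `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @param cohorts Character subset of `c("gwas", "train", "test")` to
#'   generate beyond the reference panel.
#' @return List with `config`, `annotation`, `geno_ref`, `truth`,
#'   `expression`, `ld` and, per requested cohort, `geno_<cohort>` plus the
#'   [simulate_phenotype_and_gwas()] output under `<cohort>`.
#' @export
simulate_study <- function(config,
                           cohorts = c("gwas", "train", "test")) {
  set.seed(config$seed)
  annotation <- make_annotation(config)
  geno_ref <- simulate_genotypes(config$n_ref, annotation, config)
  truth <- simulate_truth(config, geno_ref)
  expression <- simulate_expression(geno_ref, truth, config)
  out <- list(config = config, annotation = annotation,
              geno_ref = geno_ref, truth = truth, expression = expression,
              ld = ld_from_genotypes(geno_ref))
  sizes <- c(gwas = config$n_gwas, train = config$n_train,
             test = config$n_test)
  for (ch in intersect(c("gwas", "train", "test"), cohorts)) {
    g <- simulate_genotypes(sizes[[ch]], annotation, config,
                            snps = geno_ref$snps)
    out[[paste0("geno_", ch)]] <- g
    out[[ch]] <- simulate_phenotype_and_gwas(g, truth, config)
  }
  out
}
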