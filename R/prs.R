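# Gene-based polygenic scores: expression imputation, training-cohort effect
# sizes, thresholded profiles, and incremental-R^2 evaluation.

#' Default p-value threshold grid for profile construction
#'
#' @return The 17 standard predictor-selection cutoffs, strictly decreasing
#'   from 1 to 5e-8.
#' @export
prs_threshold_grid <- function() {
  c(1, 0.8, 0.5, 0.4, 0.3, 0.2, 0.1, 0.08, 0.05, 0.02, 0.01, 0.001,
    1e-4, 1e-5, 1e-6, 1e-7, 5e-8)
}

#' Impute gene expression from individual-level genotypes
#'
#' For one tissue of a weight panel, computes `E_hat = X_std %*% w` per gene
#' after harmonizing alleles between genotypes and panel (weights flipped in
#' sign where effect/other alleles are swapped; mismatches dropped).
#' Zero-variance dosage columns are excluded before standardization.
#'
#' @param genotypes An `xtwas_genotypes` object.
#' @param panel WeightPanel `data.table`.
#' @param tissue Tissue id (default: first in the panel).
#' @return Subject x gene matrix of imputed expression; genes with no
#'   usable SNP are omitted.
#' @export
impute_expression <- function(genotypes, panel, tissue = NULL) {
  if (is.null(tissue)) tissue <- panel$tissue_id[1L]
  panel <- panel[panel$tissue_id == tissue, ]
  assert_that(nrow(panel) > 0L, "tissue not present in weight panel")
  sp <- genotypes$snps
  sx <- standardize_columns(genotypes$X)
  usable <- stats::setNames(sx$keep, colnames(genotypes$X))
  Xs <- matrix(0, nrow(genotypes$X), ncol(genotypes$X),
               dimnames = dimnames(genotypes$X))
  Xs[, sx$keep] <- sx$X
  genes <- unique(panel$gene_id)
  out <- matrix(NA_real_, nrow(genotypes$X), length(genes),
                dimnames = list(NULL, genes))
  keep_gene <- logical(length(genes))
  for (gi in seq_along(genes)) {
    wt <- panel[panel$gene_id == genes[gi], ]
    gi2 <- match(wt$snp_id, sp$snp)
    ok <- !is.na(gi2)
    if (any(ok)) {
      same <- sp$a1[gi2[ok]] == wt$effect_allele[ok] &
        sp$a2[gi2[ok]] == wt$other_allele[ok]
      swap <- sp$a1[gi2[ok]] == wt$other_allele[ok] &
        sp$a2[gi2[ok]] == wt$effect_allele[ok]
      sgn <- ifelse(same, 1, ifelse(swap, -1, NA))
      use <- !is.na(sgn) & usable[wt$snp_id[ok]]
      if (any(use)) {
        cols <- wt$snp_id[ok][use]
        out[, gi] <- Xs[, cols, drop = FALSE] %*%
          (wt$weight[ok][use] * sgn[use])
        keep_gene[gi] <- TRUE
      }
    }
  }
  out[, keep_gene, drop = FALSE]
}

#' Expanded training covariate set
#'
#' Builds the fuller covariate design used when estimating gene effects in
#' the training cohort: age, age squared, sex, age x sex (and age-squared x
#' sex), mirroring standard imaging-genetics adjustment.
#'
#' @param age,sex Numeric vectors.
#' @return Covariate matrix.
#' @export
training_covariates <- function(age, sex) {
  cbind(age = age, age2 = age^2, sex = sex,
        age_sex = age * sex, age2_sex = age^2 * sex)
}

#' Estimate per-gene expression effects in a training cohort
#'
#' One OLS regression per gene of the phenotype on that gene's imputed
#' expression plus covariates (plus a total-volume-like covariate when
#' `total` is supplied), returning the expression coefficient and its
#' two-sided p-value.
#'
#' @param phenotype Training phenotype vector.
#' @param expr Subject x gene imputed expression matrix.
#' @param covariates Covariate matrix (e.g. [training_covariates()]).
#' @param total Optional extra covariate vector (total-volume rule).
#' @return A `data.table`: `gene_id, beta, se, p`. Rank-deficient designs
#'   are skipped with a message.
#' @export
train_gene_effects <- function(phenotype, expr, covariates, total = NULL) {
  covariates <- as.matrix(covariates)
  if (!is.null(total)) covariates <- cbind(covariates, total = total)
  assert_that(length(phenotype) > ncol(covariates) + 2,
              "training cohort too small for covariate set")
  rows <- vector("list", ncol(expr))
  for (g in seq_len(ncol(expr))) {
    X <- cbind(1, covariates, e = expr[, g])
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      message("rank-deficient design for gene ", colnames(expr)[g],
              "; skipped")
      next
    }
    cf <- qr.coef(qx, phenotype)
    res <- phenotype - X %*% cf
    df <- length(phenotype) - ncol(X)
    s2 <- sum(res^2) / df
    XtXinv_e <- chol2inv(qr.R(qx))[ncol(X), ncol(X)]
    se <- sqrt(s2 * XtXinv_e)
    tt <- cf[length(cf)] / se
    rows[[g]] <- data.table::data.table(
      gene_id = colnames(expr)[g], beta = unname(cf[length(cf)]),
      se = se, p = 2 * pt(-abs(tt), df = df))
  }
  data.table::rbindlist(rows)
}

#' Build thresholded polygenic profiles
#'
#' `profile_s(tau) = sum over genes with training p <= tau of
#' beta_g * E_hat[s, g]`; one profile per grid value, `tau = 1` including
#' every gene. Thresholds at which no gene passes yield an all-zero profile
#' and are flagged.
#'
#' @param expr Test-cohort subject x gene imputed expression.
#' @param effects Training effects ([train_gene_effects()]).
#' @param grid Decreasing p-value cutoffs (default [prs_threshold_grid()]).
#' @return Subject x threshold matrix with the grid as column names and an
#'   `empty` attribute flagging all-zero profiles.
#' @export
build_profiles <- function(expr, effects, grid = prs_threshold_grid()) {
  assert_that(length(grid) >= 1L, "empty threshold grid")
  common <- intersect(colnames(expr), effects$gene_id)
  eff <- effects[match(common, effects$gene_id), ]
  E <- expr[, common, drop = FALSE]
  out <- matrix(0, nrow(expr), length(grid),
                dimnames = list(NULL, sprintf("%g", grid)))
  empty <- logical(length(grid))
  for (i in seq_along(grid)) {
    sel <- eff$p <= grid[i]
    if (!any(sel)) {
      empty[i] <- TRUE
      next
    }
    out[, i] <- E[, sel, drop = FALSE] %*% eff$beta[sel]
  }
  attr(out, "empty") <- empty
  out
}

#' Variant-based GWAS polygenic score by p-value thresholding
#'
#' Simple clumping-free score: standardized dosages weighted by the
#' GWAS-estimated standardized effect `z / sqrt(n)` for SNPs passing the
#' threshold.
#'
#' @param genotypes An `xtwas_genotypes` object.
#' @param gwas GWAS summary table.
#' @param p_cut Inclusion threshold (default 1e-3).
#' @return Numeric score vector (zeros if no SNP passes).
#' @export
build_gwas_prs <- function(genotypes, gwas, p_cut = 1e-3) {
  gi <- match(colnames(genotypes$X), gwas$snp)
  w <- ifelse(!is.na(gi) & gwas$p[gi] <= p_cut, gwas$z[gi] / sqrt(gwas$n[gi]),
              0)
  w[is.na(w)] <- 0
  if (all(w == 0)) return(rep(0, nrow(genotypes$X)))
  sx <- standardize_columns(genotypes$X)
  as.vector(sx$X %*% w[sx$keep])
}

#' Incremental R-squared of polygenic profiles
#'
#' Fits the four nested OLS models `m1: y ~ covariates`,
#' `m2: + TWAS profile`, `m3: + GWAS PRS`, `m4: + both` in the test cohort
#' (covariates: age and sex only) and reports, per threshold, the increments
#' `m2 - m1` (TWAS), `m3 - m1` (GWAS), `m4 - m1` (joint), `m4 - m3`
#' (TWAS | GWAS), `m4 - m2` (GWAS | TWAS) and the profile coefficient's
#' two-sided p-value in m2. An all-zero profile yields exactly zero
#' increments.
#'
#' @param phenotype Test phenotype (non-constant).
#' @param profiles Subject x threshold matrix ([build_profiles()]).
#' @param covariates Test-cohort covariate matrix (age, sex).
#' @param gwas_prs Optional variant-based score for the joint models; when
#'   absent the GWAS/joint columns are `NA`.
#' @return A `data.table` with one row per threshold plus attribute `best`
#'   (maximum TWAS increment over the grid).
#' @export
evaluate_incremental_r2 <- function(phenotype, profiles, covariates,
                                    gwas_prs = NULL) {
  assert_that(stats::var(phenotype) > 0, "constant phenotype")
  covariates <- as.matrix(covariates)
  r2 <- function(X) {
    q <- qr(cbind(1, X))
    1 - sum(qr.resid(q, phenotype)^2) /
      sum((phenotype - mean(phenotype))^2)
  }
  coef_p <- function(X) {
    q <- qr(cbind(1, X))
    if (q$rank < ncol(X) + 1) return(NA_real_)
    cf <- qr.coef(q, phenotype)
    res <- qr.resid(q, phenotype)
    df <- length(phenotype) - q$rank
    se <- sqrt(sum(res^2) / df * chol2inv(qr.R(q))[ncol(X) + 1, ncol(X) + 1])
    2 * pt(-abs(cf[length(cf)] / se), df = df)
  }
  m1 <- r2(covariates)
  m3 <- if (!is.null(gwas_prs)) r2(cbind(covariates, gwas_prs)) else NA_real_
  rows <- vector("list", ncol(profiles))
  for (i in seq_len(ncol(profiles))) {
    pr <- profiles[, i]
    if (all(pr == 0)) {
      m2 <- m1
      m4 <- m3
      pcoef <- NA_real_
    } else {
      m2 <- r2(cbind(covariates, pr))
      m4 <- if (!is.null(gwas_prs)) {
        r2(cbind(covariates, pr, gwas_prs))
      } else NA_real_
      pcoef <- coef_p(cbind(covariates, pr))
    }
    rows[[i]] <- data.table::data.table(
      threshold = colnames(profiles)[i],
      r2_twas = m2 - m1,
      r2_gwas = m3 - m1,
      r2_joint = m4 - m1,
      r2_twas_given_gwas = m4 - m3,
      r2_gwas_given_twas = m4 - m2,
      p_profile = pcoef)
  }
  out <- data.table::rbindlist(rows)
  attr(out, "best") <- max(out$r2_twas)
  out
}

#' Multiplicity bookkeeping for PRS evaluation
#'
#' @param n_roi_traits,n_roi_cohorts,n_dti_traits,n_dti_cohorts Positive
#'   counts.
#' @param alpha Family-wise level (default 0.05).
#' @return List: `n_tests = n_roi_traits * n_roi_cohorts +
#'   n_dti_traits * n_dti_cohorts` and `threshold = alpha / n_tests`.
#' @export
#' @examples
#' prs_multiplicity(101, 4, 110, 3)  # 734 tests
prs_multiplicity <- function(n_roi_traits, n_roi_cohorts,
                             n_dti_traits, n_dti_cohorts, alpha = 0.05) {
  assert_that(all(c(n_roi_traits, n_roi_cohorts, n_dti_traits,
                    n_dti_cohorts) >= 1), "counts must be positive")
  n <- n_roi_traits * n_roi_cohorts + n_dti_traits * n_dti_cohorts
  list(n_tests = n, threshold = alpha / n)
}
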