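# Cross-tissue imputation weight training: sparse group lasso by block
# coordinate descent. Groups are SNPs across tissues, so a penalized SNP is
# either dropped from every tissue or kept (with tissue-specific effects) in
# several — the "within-tissue and cross-tissue" penalty structure used by
# multi-tissue expression imputation models.

# Soft-threshold operator.
#' @noRd
soft <- function(x, a) sign(x) * pmax(abs(x) - a, 0)

# Objective: sum_t (1/(2 N)) ||y_t - X b_t||^2
#            + l1 * sum |b| + lg * sum_j ||b[j, ]||_2
#' @noRd
sgl_objective <- function(Xs, Ys, B, l1, lg) {
  n <- nrow(Xs)
  R <- Ys - Xs %*% B
  sum(R^2) / (2 * n) + l1 * sum(abs(B)) + lg * sum(sqrt(rowSums(B^2)))
}

# Max KKT violation of the sparse-group-lasso stationarity conditions.
#' @noRd
sgl_kkt <- function(Xs, Ys, B, l1, lg) {
  n <- nrow(Xs)
  G <- crossprod(Xs, Xs %*% B - Ys) / n      # gradient of the smooth part
  viol <- 0
  for (j in seq_len(nrow(B))) {
    bj <- B[j, ]
    if (any(bj != 0)) {
      nb <- sqrt(sum(bj^2))
      sub <- G[j, ] + l1 * ifelse(bj != 0, sign(bj),
                                  pmin(pmax(-G[j, ] / max(l1, 1e-300), -1), 1)) +
        lg * bj / nb
      sub[bj == 0] <- pmax(abs(G[j, bj == 0]) - l1, 0)
      viol <- max(viol, max(abs(sub[bj != 0])), max(sub[bj == 0], 0))
    } else {
      viol <- max(viol, sqrt(sum(soft(-G[j, ], l1)^2)) - lg)
    }
  }
  max(viol, 0)
}

#' Train cross-tissue expression imputation weights for one gene
#'
#' Minimizes the multi-tissue sparse-group-lasso objective
#' \deqn{\sum_t \frac{1}{2N}\|y_t - X\beta_t\|^2
#'       + \lambda_1 \sum_{j,t} |\beta_{jt}|
#'       + \lambda_g \sum_j \|\beta_{j\cdot}\|_2}
#' by block coordinate descent over SNPs. Genotypes and expression are
#' standardized internally (population scale), so the design has exactly
#' unit column norms and each block update is the closed-form group
#' soft-threshold; the objective is therefore non-increasing at every sweep.
#' Returned weights are on the standardized-genotype scale, so the
#' summary-statistic test statistic `w'z / sqrt(w'Dw)` applies directly with
#' `D` a SNP correlation matrix.
#'
#' @param expression Numeric matrix (subjects x tissues) of one gene's
#'   expression, or a list of per-tissue vectors over the same subjects.
#' @param genotypes Numeric matrix (subjects x SNPs) of cis dosages, with
#'   column names.
#' @param lambda_lasso,lambda_group Non-negative penalties.
#' @param max_iter,tol Convergence controls: stop when the relative
#'   objective decrease falls below `tol` (KKT residual then checked
#'   against `10 * tol`).
#' @return List: `beta` (SNP x tissue matrix, standardized scale),
#'   `objective` (trace), `converged`, `kkt`, `iterations`.
#' @export
train_cross_tissue <- function(expression, genotypes,
                               lambda_lasso = 0.05, lambda_group = 0.05,
                               max_iter = 1000L, tol = 1e-7) {
  if (is.list(expression) && !is.matrix(expression)) {
    expression <- do.call(cbind, expression)
  }
  assert_that(lambda_lasso >= 0 && lambda_group >= 0,
              "penalties must be non-negative")
  assert_that(nrow(expression) == nrow(genotypes),
              "expression and genotypes have different subject counts")
  sx <- standardize_columns(genotypes)
  Xs <- sx$X
  Ys <- apply(as.matrix(expression), 2L, function(y) {
    yc <- y - mean(y); s <- sqrt(mean(yc^2)); if (s > 0) yc / s else yc
  })
  p <- ncol(Xs); Tt <- ncol(Ys); n <- nrow(Xs)
  C <- crossprod(Xs) / n                 # unit diagonal by construction
  A <- crossprod(Xs, Ys) / n
  B <- matrix(0, p, Tt, dimnames = list(colnames(Xs), colnames(expression)))
  obj <- sgl_objective(Xs, Ys, B, lambda_lasso, lambda_group)
  trace <- obj
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (j in seq_len(p)) {
      cj <- A[j, ] - C[j, ] %*% B + B[j, ]
      s <- soft(as.vector(cj), lambda_lasso)
      ns <- sqrt(sum(s^2))
      B[j, ] <- if (ns <= lambda_group) 0 else s * (1 - lambda_group / ns)
    }
    obj_new <- sgl_objective(Xs, Ys, B, lambda_lasso, lambda_group)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(abs(obj), 1e-12)) {
      # objective has flattened; accept only once stationarity holds too
      if (sgl_kkt(Xs, Ys, B, lambda_lasso, lambda_group) <= 10 * tol) {
        converged <- TRUE
        obj <- obj_new
        break
      }
    }
    obj <- obj_new
  }
  kkt <- sgl_kkt(Xs, Ys, B, lambda_lasso, lambda_group)
  if (!converged) {
    warning("sparse-group solver did not converge within max_iter; ",
            "partial result returned")
  }
  # map back to full SNP set (zero-variance columns get zero weight)
  Bfull <- matrix(0, length(sx$keep), Tt,
                  dimnames = list(colnames(genotypes), colnames(B)))
  Bfull[sx$keep, ] <- B
  list(beta = Bfull, objective = trace, converged = converged,
       kkt = kkt, iterations = it)
}

#' Cross-validate sparse-group penalties
#'
#' Folds are assigned by a seeded permutation of subjects; the chosen grid
#' point minimizes mean held-out squared error summed over tissues, with
#' ties broken toward the sparser (larger total penalty) model.
#'
#' @param expression Subjects x tissues matrix for one gene.
#' @param genotypes Subjects x SNPs dosage matrix.
#' @param grid Data frame with columns `lambda_lasso`, `lambda_group`.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the fold permutation.
#' @return List: `lambda_lasso`, `lambda_group`, and `cv` (the grid with a
#'   `cv_error` column).
#' @export
cross_validate_penalties <- function(expression, genotypes, grid,
                                     n_folds = 5L, seed = 1L) {
  assert_that(NROW(grid) >= 1L, "penalty grid is empty")
  assert_that(n_folds >= 2L, "n_folds must be at least 2")
  if (is.list(expression) && !is.matrix(expression)) {
    expression <- do.call(cbind, expression)
  }
  grid <- as.data.frame(grid)
  grid <- grid[order(grid$lambda_lasso + grid$lambda_group,
                     decreasing = TRUE), , drop = FALSE]
  n <- nrow(genotypes)
  old <- .Random.seed_save()
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  .Random.seed_restore(old)
  err <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    se <- 0
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- train_cross_tissue(expression[tr, , drop = FALSE],
                                genotypes[tr, , drop = FALSE],
                                grid$lambda_lasso[g], grid$lambda_group[g])
      mu <- colMeans(genotypes[tr, , drop = FALSE])
      sd0 <- sqrt(colMeans(sweep(genotypes[tr, , drop = FALSE], 2, mu)^2))
      sd0[sd0 == 0] <- 1
      Xte <- sweep(sweep(genotypes[!tr, , drop = FALSE], 2, mu), 2, sd0, "/")
      Ete <- apply(expression[!tr, , drop = FALSE], 2L,
                   function(y) y - mean(y))
      se <- se + sum((Ete - Xte %*% fit$beta)^2) / sum(!tr)
    }
    err[g] <- se / n_folds
  }
  best <- which.min(err)
  list(lambda_lasso = grid$lambda_lasso[best],
       lambda_group = grid$lambda_group[best],
       cv = cbind(grid, cv_error = err))
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Train a weight panel for every gene of a simulated study
#'
#' @param sim A [simulate_study()] result.
#' @param lambda_lasso,lambda_group Penalties passed to
#'   [train_cross_tissue()].
#' @return A `data.table` WeightPanel:
#'   `gene_id, tissue_id, snp_id, effect_allele, other_allele, weight`
#'   (nonzero weights only, standardized-genotype scale).
#' @export
train_weight_panel <- function(sim, lambda_lasso = 0.05,
                               lambda_group = 0.05) {
  sp <- sim$geno_ref$snps
  tissues <- names(sim$expression)
  rows <- list()
  for (g in unique(sp$gene_id)) {
    idx <- which(sp$gene_id == g)
    E <- vapply(sim$expression, function(m) m[, g], numeric(config_n(sim)))
    fit <- train_cross_tissue(E, sim$geno_ref$X[, idx, drop = FALSE],
                              lambda_lasso, lambda_group)
    nz <- which(fit$beta != 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) next
    rows[[g]] <- data.table::data.table(
      gene_id = g,
      tissue_id = tissues[nz[, 2L]],
      snp_id = sp$snp[idx][nz[, 1L]],
      effect_allele = sp$a1[idx][nz[, 1L]],
      other_allele = sp$a2[idx][nz[, 1L]],
      weight = fit$beta[nz])
  }
  panel <- data.table::rbindlist(rows)
  validate_weight_panel(panel, sp$snp)
  panel
}

#' @noRd
config_n <- function(sim) nrow(sim$geno_ref$X)

#' Oracle weight panel from the generator's truth
#'
#' Converts the true per-gene eQTL effect matrices of a simulated study into
#' a WeightPanel table (standardized-genotype scale). Useful as the
#' best-possible imputation model in calibration and power studies, where
#' training noise would only dilute the quantity under test.
#'
#' @param sim A [simulate_study()] result.
#' @return A WeightPanel `data.table` (nonzero weights only).
#' @export
oracle_weight_panel <- function(sim) {
  sp <- sim$geno_ref$snps
  tissues <- names(sim$expression)
  rows <- list()
  for (g in sim$truth$genes) {
    B <- sim$truth$effects[[g]]
    nz <- which(B != 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) next
    gi <- match(rownames(B)[nz[, 1L]], sp$snp)
    rows[[g]] <- data.table::data.table(
      gene_id = g, tissue_id = tissues[nz[, 2L]],
      snp_id = sp$snp[gi], effect_allele = sp$a1[gi],
      other_allele = sp$a2[gi], weight = B[nz])
  }
  panel <- data.table::rbindlist(rows)
  validate_weight_panel(panel, sp$snp)
  panel
}

#' Validate a WeightPanel table
#'
#' Checks the panel invariants: no duplicate (gene, tissue, snp) triple,
#' every SNP known, and at least one nonzero weight per stored pair.
#' @param panel WeightPanel `data.table`.
#' @param known_snps Character vector of valid SNP ids (optional).
#' @return Invisibly, the panel.
#' @export
validate_weight_panel <- function(panel, known_snps = NULL) {
  assert_that(!anyDuplicated(panel[, c("gene_id", "tissue_id", "snp_id")]),
              "duplicate (gene, tissue, snp) triple in weight panel")
  if (!is.null(known_snps)) {
    assert_that(all(panel$snp_id %in% known_snps),
                "weight panel contains unknown SNPs")
  }
  byp <- tapply(panel$weight, paste(panel$gene_id, panel$tissue_id),
                function(w) any(w != 0))
  assert_that(all(byp), "stored (gene, tissue) pair with all-zero weights")
  invisible(panel)
}
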