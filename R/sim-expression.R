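# Multi-tissue eQTL architecture and expression simulation.

#' Draw the causal architecture of a simulated study
#'
#' For each gene, `n_causal_eqtl_per_gene` cis SNPs receive eQTL effects
#' shared across tissues through a one-factor model:
#' `b[j, t] = sqrt(rho_ct) * u[j] + sqrt(1 - rho_ct) * v[j, t]`, giving
#' cross-tissue effect correlation `rho_ct = cross_tissue_cor`. Per-tissue
#' effects are rescaled on the reference genotypes so the genetic share of
#' expression variance equals `cis_h2`. Gene-level mediation effects `alpha`
#' and direct SNP effects are scaled the same way to hit `mediated_h2` and
#' `direct_h2` on the reference sample; realized shares in an independent
#' cohort agree up to sampling error.
#'
#' @param config An [sim_config()] object.
#' @param geno_ref Reference-panel genotypes ([simulate_genotypes()]).
#' @return An `xtwas_truth` object: per-gene causal index sets and SNP x
#'   tissue effect matrices, mediation effects `alpha`, a named vector of
#'   direct SNP effects, and the configured variance targets.
#' @export
simulate_truth <- function(config, geno_ref) {
  sp <- geno_ref$snps
  genes <- unique(sp$gene_id)
  Xs <- standardize_columns(geno_ref$X)$X
  rho <- config$cross_tissue_cor
  Tt <- config$n_tissues
  effects <- vector("list", length(genes))
  names(effects) <- genes
  causal <- effects
  gvalue <- matrix(0, nrow(Xs), length(genes))
  for (gi in seq_along(genes)) {
    idx <- which(sp$gene_id == genes[gi])
    p <- length(idx)
    cs <- sort(sample(p, config$n_causal_eqtl_per_gene))
    B <- matrix(0, p, Tt, dimnames = list(sp$snp[idx], NULL))
    if (config$cis_h2 > 0) {
      u <- rnorm(length(cs))
      V <- matrix(rnorm(length(cs) * Tt), length(cs), Tt)
      B[cs, ] <- sqrt(rho) * u + sqrt(1 - rho) * V
      G <- Xs[, idx, drop = FALSE] %*% B
      sc <- sqrt(config$cis_h2) / sqrt(colMeans(sweep(G, 2, colMeans(G))^2))
      B <- sweep(B, 2L, sc, "*")
    }
    effects[[gi]] <- B
    causal[[gi]] <- sp$snp[idx][cs]
    bbar <- rowMeans(B)
    gvalue[, gi] <- Xs[, idx, drop = FALSE] %*% bbar
  }
  alpha <- stats::setNames(rep(0, length(genes)), genes)
  if (config$mediated_h2 > 0 && config$cis_h2 > 0) {
    a0 <- rnorm(length(genes))
    m <- gvalue %*% a0
    alpha[] <- a0 * sqrt(config$mediated_h2) / sqrt(mean((m - mean(m))^2))
  }
  direct <- stats::setNames(rep(0, nrow(sp)), sp$snp)
  if (config$direct_h2 > 0) {
    nd <- max(1L, ceiling(0.1 * nrow(sp)))
    dj <- sample(nrow(sp), nd)
    d0 <- rnorm(nd)
    dv <- Xs[, dj, drop = FALSE] %*% d0
    direct[dj] <- d0 * sqrt(config$direct_h2) / sqrt(mean((dv - mean(dv))^2))
  }
  structure(list(genes = genes, causal = causal, effects = effects,
                 alpha = alpha, direct = direct,
                 mediated_h2 = config$mediated_h2,
                 direct_h2 = config$direct_h2, cis_h2 = config$cis_h2),
            class = "xtwas_truth")
}

#' Simulate multi-tissue expression
#'
#' Expression in tissue t is `X_std %*% b_t` plus Gaussian noise with
#' variance `1 - cis_h2`, so total variance is about 1 and the genetic share
#' matches `cis_h2`. With `cis_h2 = 0` expression is pure noise; with
#' `cross_tissue_cor = 1` the genetic values coincide across tissues.
#'
#' @param genotypes Cohort genotypes whose SNP set matches `truth`.
#' @param truth An `xtwas_truth` object.
#' @param config An [sim_config()] object.
#' @return Named list (tissue1..tissueT) of subject x gene expression
#'   matrices.
#' @export
simulate_expression <- function(genotypes, truth, config) {
  assert_that(config$cis_h2 >= 0 && config$cis_h2 < 1,
              "cis_h2 must be in [0, 1)")
  assert_that(identical(colnames(genotypes$X),
                        unlist(lapply(truth$effects, rownames),
                               use.names = FALSE)),
              "truth effects do not conform to genotype SNP set")
  Xs <- standardize_columns(genotypes$X)$X
  n <- nrow(Xs)
  sp <- genotypes$snps
  out <- lapply(seq_len(config$n_tissues), function(t) {
    E <- matrix(0, n, length(truth$genes),
                dimnames = list(NULL, truth$genes))
    for (gi in seq_along(truth$genes)) {
      idx <- which(sp$gene_id == truth$genes[gi])
      E[, gi] <- Xs[, idx, drop = FALSE] %*% truth$effects[[gi]][, t] +
        rnorm(n, sd = sqrt(1 - config$cis_h2))
    }
    E
  })
  names(out) <- sprintf("tissue%02d", seq_len(config$n_tissues))
  out
}
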