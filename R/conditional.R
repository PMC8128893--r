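# Conditional analysis: re-test imputed-expression association adjusting for
# the strongest GWAS variant in the imputation model, via partial-correlation
# algebra on summary statistics.

#' Most significant model variant for a gene-tissue pair
#'
#' Among SNPs carrying nonzero weight in the gene-tissue model and present
#' in the GWAS, returns the one with the smallest GWAS p-value; ties are
#' broken by smaller position, then lexicographic id.
#'
#' @param weights Weight rows for one gene-tissue pair (`snp_id, weight`).
#' @param gwas GWAS summary table (`snp, pos, p`).
#' @return Variant id, or `NA_character_` (with a warning) if no model SNP
#'   overlaps the GWAS.
#' @export
pick_top_model_variant <- function(weights, gwas) {
  snps <- weights$snp_id[weights$weight != 0]
  gi <- match(snps, gwas$snp)
  ok <- !is.na(gi)
  if (!any(ok)) {
    warning("no model SNP present in GWAS; pair skipped")
    return(NA_character_)
  }
  sub <- gwas[gi[ok], ]
  ord <- order(sub$p, sub$pos, sub$snp)
  sub$snp[ord[1L]]
}

#' Conditional association of imputed expression given one variant
#'
#' Summary-statistic realization of the individual-level regression
#' `phenotype ~ imputed expression + variant`: with
#' `r_Ey = z_E / sqrt(n)`, `r_vy = z_v / sqrt(n)` and
#' `r_Ev = (D w)_v / sqrt(w' D w)` (the LD-implied correlation between the
#' imputed expression and the conditioned variant), the partial correlation
#' \deqn{r_{Ey \cdot v} = \frac{r_{Ey} - r_{Ev} r_{vy}}
#'   {\sqrt{(1 - r_{Ev}^2)(1 - r_{vy}^2)}}}
#' gives the conditional t-statistic
#' `t = r * sqrt((n - 3) / (1 - r^2))`, mapped to a z-score through its
#' p-value. A gene imputed (near-)collinearly with the variant is flagged
#' `fully_explained` with `p = 1`.
#'
#' @param w Aligned weight vector.
#' @param z Aligned GWAS z-scores.
#' @param D SNP correlation matrix.
#' @param v Index (or SNP id position) of the conditioned variant within the
#'   aligned SNP set.
#' @param n GWAS sample size (> 3).
#' @param collinear_tol Collinearity guard on `|r_Ev|` (default `1 - 1e-6`).
#' @return List: `z`, `p`, `t`, `df`, `r_partial`, `r_Ev`, `flag`
#'   (`"ok"` or `"fully_explained"`).
#' @export
conditional_z <- function(w, z, D, v, n, collinear_tol = 1 - 1e-6) {
  assert_that(n > 3, "n must exceed 3")
  q <- as.numeric(crossprod(w, D %*% w))
  assert_that(q > 0, "degenerate imputation model")
  z_E <- sum(w * z) / sqrt(q)
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  r_Ey <- clamp(z_E / sqrt(n))
  r_vy <- clamp(z[v] / sqrt(n))
  r_Ev <- as.numeric(D[v, ] %*% w) / sqrt(q)
  if (abs(r_Ev) >= collinear_tol) {
    return(list(z = 0, p = 1, t = 0, df = n - 3, r_partial = 0,
                r_Ev = r_Ev, flag = "fully_explained"))
  }
  r <- (r_Ey - r_Ev * r_vy) / sqrt((1 - r_Ev^2) * (1 - r_vy^2))
  r <- clamp(r)
  tt <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = n - 3)
  zz <- sign(tt) * qnorm(pmax(p / 2, 1e-320), lower.tail = FALSE)
  list(z = zz, p = p, t = tt, df = n - 3, r_partial = r, r_Ev = r_Ev,
       flag = "ok")
}

#' @noRd
persistence_class <- function(p) {
  if (p > 0.05) "p>0.05"
  else if (p > 1e-3) "0.001<p<=0.05"
  else if (p > 1e-6) "p<=1e-3"
  else "p<=1e-6"
}

#' Combine per-tissue conditional statistics for one gene
#'
#' Applies the generalized Berk-Jones combination to the conditional
#' z-vector, reusing the same tissue covariance as the marginal test, and
#' assigns a persistence class from the combined p-value: `p>0.05`
#' (association dominated by the single variant), `0.001<p<=0.05`,
#' `p<=1e-3`, `p<=1e-6` (multi-variant signal). If every tissue was
#' collinear-flagged the class is `fully_explained`.
#'
#' @param cond List of [conditional_z()] results (one per tissue).
#' @param sigma Tissue correlation matrix from the marginal analysis.
#' @param B,seed Monte-Carlo controls for [gbj_pvalue()].
#' @return List: `p_gbj`, `stat`, `class`, `n_tissues`.
#' @export
combine_conditional <- function(cond, sigma, B = 2000L, seed = 1L) {
  assert_that(length(cond) >= 1L, "no tissue results")
  flags <- vapply(cond, `[[`, character(1), "flag")
  if (all(flags == "fully_explained")) {
    return(list(p_gbj = 1, stat = 0, class = "fully_explained",
                n_tissues = length(cond)))
  }
  zv <- vapply(cond, `[[`, numeric(1), "z")
  pv <- if (length(zv) == 1L) {
    gbj_pvalue(zv, diag(1), B = B, seed = seed)
  } else {
    gbj_pvalue(zv, as.matrix(sigma), B = B, seed = seed)
  }
  list(p_gbj = pv$p, stat = pv$stat, class = persistence_class(pv$p),
       n_tissues = length(zv))
}
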