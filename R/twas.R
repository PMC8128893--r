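# Single-panel summary-statistic TWAS with allele harmonization.

AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize weight, GWAS and LD records for one gene-tissue pair
#'
#' Keys every record to the weight panel's effect allele. GWAS z-scores are
#' sign-flipped where effect/other alleles are swapped relative to the panel;
#' SNPs whose allele pairs cannot be reconciled are dropped; strand-ambiguous
#' (A/T, C/G) SNPs are dropped when `drop_ambiguous` is set. LD rows/columns
#' are sign-flipped consistently. Input row order does not affect the result
#' (output follows the weight-table order after filtering).
#'
#' @param weights Weight rows for one gene-tissue pair
#'   (`snp_id, effect_allele, other_allele, weight`).
#' @param gwas GWAS summary table (`snp, a1, a2, z`, ...).
#' @param ld LD reference for the gene: list with `snps`, `a1`, `a2`,
#'   matrix `D`.
#' @param drop_ambiguous Drop strand-ambiguous SNPs (default TRUE).
#' @return List: `snps`, `w`, `z`, `D` (aligned), and `drop_log` (a
#'   `data.table` of dropped SNPs with reasons). Errors if no SNP survives.
#' @export
harmonize_alleles <- function(weights, gwas, ld, drop_ambiguous = TRUE) {
  weights <- as.data.frame(weights)
  gwas <- as.data.frame(gwas)
  gi <- match(weights$snp_id, gwas$snp)
  li <- match(weights$snp_id, ld$snps)
  drop <- character(nrow(weights))
  drop[is.na(gi)] <- "absent_gwas"
  drop[is.na(li) & drop == ""] <- "absent_ld"
  pair <- paste(weights$effect_allele, weights$other_allele, sep = "/")
  if (drop_ambiguous) {
    drop[drop == "" & pair %in% AMBIGUOUS_PAIRS] <- "ambiguous"
  }
  flip_g <- rep(FALSE, nrow(weights))
  flip_l <- rep(FALSE, nrow(weights))
  ok <- drop == ""
  for (i in which(ok)) {
    wa <- c(weights$effect_allele[i], weights$other_allele[i])
    ga <- c(gwas$a1[gi[i]], gwas$a2[gi[i]])
    la <- c(ld$a1[li[i]], ld$a2[li[i]])
    if (identical(ga, wa)) {
    } else if (identical(ga, rev(wa))) flip_g[i] <- TRUE
    else { drop[i] <- "allele_mismatch"; next }
    if (identical(la, wa)) {
    } else if (identical(la, rev(wa))) flip_l[i] <- TRUE
    else drop[i] <- "allele_mismatch"
  }
  keep <- drop == ""
  if (!any(keep)) {
    stop("no SNP left after harmonization", call. = FALSE)
  }
  zs <- gwas$z[gi[keep]] * ifelse(flip_g[keep], -1, 1)
  sgn <- ifelse(flip_l[keep], -1, 1)
  D <- ld$D[li[keep], li[keep], drop = FALSE] * tcrossprod(sgn)
  diag(D) <- 1
  list(snps = weights$snp_id[keep], w = weights$weight[keep], z = zs, D = D,
       drop_log = data.table::data.table(snp = weights$snp_id[!keep],
                                         reason = drop[!keep]))
}

#' Single-tissue TWAS z-statistic from summary statistics
#'
#' The standard summary-statistic TWAS statistic
#' \deqn{z_{TWAS} = \frac{w' z}{\sqrt{w'(D + \epsilon I)w}}}
#' with weights on the standardized-genotype scale and `D` the SNP
#' correlation matrix from an LD reference. A small ridge stabilizes the
#' quadratic form when `D` is estimated.
#'
#' @param w Aligned weight vector (at least one nonzero entry).
#' @param z Aligned GWAS z-scores.
#' @param D SNP correlation matrix.
#' @param ridge Diagonal ridge (default 1e-6).
#' @return List: `z` (the statistic), `p` (two-sided normal), `n_snps`.
#' @export
twas_z <- function(w, z, D, ridge = 1e-6) {
  assert_that(length(w) == length(z) && length(w) == nrow(D),
              "non-conformable inputs")
  assert_that(any(w != 0), "zero weight vector")
  q <- as.numeric(crossprod(w, (D + ridge * diag(length(w))) %*% w))
  assert_that(is.finite(q) && q > 0,
              "non-positive quadratic form: LD matrix not PSD after ridge")
  zt <- sum(w * z) / sqrt(q)
  list(z = zt, p = 2 * pnorm(-abs(zt)), n_snps = sum(w != 0))
}

#' Run single-tissue TWAS over a weight panel
#'
#' Applies [harmonize_alleles()] and [twas_z()] per gene-tissue pair. A pair
#' is skipped (and logged) when no SNPs survive harmonization or when more
#' than `max_drop_mass` of the absolute weight mass is dropped.
#'
#' @param panel WeightPanel `data.table`.
#' @param gwas GWAS summary table.
#' @param ld Named list of per-gene LD references ([ld_from_genotypes()]).
#' @param ridge Ridge passed to [twas_z()].
#' @param max_drop_mass Maximum droppable fraction of absolute weight mass
#'   (default 0.5).
#' @param drop_ambiguous Passed to [harmonize_alleles()].
#' @return A `data.table` of single-tissue results:
#'   `gene_id, tissue_id, z, p, n_snps_used, top_variant` (the model SNP with
#'   the smallest GWAS p-value), with skipped pairs in
#'   `attr(, "skip_log")`.
#' @export
run_twas <- function(panel, gwas, ld, ridge = 1e-6, max_drop_mass = 0.5,
                     drop_ambiguous = TRUE) {
  keys <- unique(panel[, c("gene_id", "tissue_id")])
  rows <- vector("list", nrow(keys))
  skips <- list()
  for (i in seq_len(nrow(keys))) {
    g <- keys$gene_id[i]; tt <- keys$tissue_id[i]
    wt <- panel[panel$gene_id == g & panel$tissue_id == tt, ]
    if (is.null(ld[[g]])) {
      skips[[length(skips) + 1L]] <- data.table::data.table(
        gene_id = g, tissue_id = tt, reason = "no_ld_reference")
      next
    }
    al <- tryCatch(
      harmonize_alleles(wt, gwas, ld[[g]], drop_ambiguous = drop_ambiguous),
      error = function(e) NULL)
    if (is.null(al) || all(al$w == 0) ||
        1 - sum(abs(al$w)) / sum(abs(wt$weight)) > max_drop_mass) {
      skips[[length(skips) + 1L]] <- data.table::data.table(
        gene_id = g, tissue_id = tt, reason = "harmonization_loss")
      next
    }
    res <- twas_z(al$w, al$z, al$D, ridge = ridge)
    gp <- gwas$p[match(al$snps[al$w != 0], gwas$snp)]
    rows[[i]] <- data.table::data.table(
      gene_id = g, tissue_id = tt, z = res$z, p = res$p,
      n_snps_used = res$n_snps,
      top_variant = al$snps[al$w != 0][which.min(gp)])
  }
  out <- data.table::rbindlist(rows)
  attr(out, "skip_log") <- data.table::rbindlist(skips)
  out
}
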