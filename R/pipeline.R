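# Gene-level assembly helpers shared by the combine/conditional stages.

#' Aligned multi-tissue weight matrix for one gene
#'
#' Harmonizes the union of a gene's model SNPs (across the requested
#' tissues) against the GWAS and LD reference once, then assembles the SNP x
#' tissue weight matrix on that shared aligned SNP set (zero where a tissue
#' does not use a SNP, sign-flipped where a tissue's stored orientation
#' differs from the reference orientation).
#'
#' @param panel WeightPanel `data.table`.
#' @param gene Gene id.
#' @param tissues Character vector of tissues to include.
#' @param gwas GWAS summary table.
#' @param ld_gene LD reference entry for the gene.
#' @param drop_ambiguous Passed to [harmonize_alleles()].
#' @return List: `snps`, `W` (SNP x tissue), `z` (aligned GWAS z), `D`.
#' @export
aligned_weight_matrix <- function(panel, gene, tissues, gwas, ld_gene,
                                  drop_ambiguous = TRUE) {
  sub <- panel[panel$gene_id == gene & panel$tissue_id %in% tissues, ]
  assert_that(nrow(sub) > 0L, "gene/tissues not present in panel")
  ref <- sub[!duplicated(sub$snp_id),
             c("snp_id", "effect_allele", "other_allele")]
  ref$weight <- 1   # placeholder so the harmonizer keeps every SNP
  al <- harmonize_alleles(ref, gwas, ld_gene, drop_ambiguous)
  W <- matrix(0, length(al$snps), length(tissues),
              dimnames = list(al$snps, tissues))
  for (tt in tissues) {
    st <- sub[sub$tissue_id == tt, ]
    i <- match(st$snp_id, al$snps)
    ok <- !is.na(i)
    ri <- match(st$snp_id, ref$snp_id)
    sgn <- ifelse(st$effect_allele == ref$effect_allele[ri], 1, -1)
    W[i[ok], tt] <- st$weight[ok] * sgn[ok]
  }
  list(snps = al$snps, W = W, z = al$z, D = al$D)
}

#' Cross-tissue conditional analysis over a weight panel
#'
#' For each gene: aligns weights, GWAS and LD; per tissue, conditions the
#' imputed-expression association on the model's most significant GWAS
#' variant ([pick_top_model_variant()], [conditional_z()]); recombines the
#' conditional z-vector with the generalized Berk-Jones test using the same
#' tissue covariance as the marginal analysis ([combine_conditional()]).
#'
#' @param panel WeightPanel `data.table`.
#' @param gwas GWAS summary table.
#' @param ld Named per-gene LD list.
#' @param n GWAS sample size.
#' @param tissues Optional tissue subset.
#' @param B,seed Monte-Carlo controls.
#' @return A `data.table` with one row per gene x tissue:
#'   `gene_id, tissue_id, variant, z_cond, p_cond, flag, p_gbj, class`.
#' @export
run_conditional <- function(panel, gwas, ld, n, tissues = NULL,
                            B = 2000L, seed = 1L) {
  rows <- list()
  for (g in unique(panel$gene_id)) {
    tis <- tissues %||% unique(panel$tissue_id[panel$gene_id == g])
    al <- tryCatch(aligned_weight_matrix(panel, g, tis, gwas, ld[[g]]),
                   error = function(e) NULL)
    if (is.null(al)) next
    use <- colnames(al$W)[colSums(al$W != 0) > 0]
    if (!length(use)) next
    cond <- list()
    vids <- character()
    for (tt in use) {
      w <- al$W[, tt]
      vid <- pick_top_model_variant(
        data.table::data.table(snp_id = al$snps, weight = w), gwas)
      if (is.na(vid)) next
      cond[[tt]] <- conditional_z(w, al$z, al$D, match(vid, al$snps), n)
      vids[tt] <- vid
    }
    if (!length(cond)) next
    sigma <- if (length(cond) > 1L) {
      tissue_covariance(al$W[, names(cond), drop = FALSE], al$D)$sigma
    } else diag(1)
    cb <- combine_conditional(cond, sigma, B = B, seed = seed)
    rows[[g]] <- data.table::data.table(
      gene_id = g, tissue_id = names(cond), variant = unname(vids),
      z_cond = vapply(cond, `[[`, numeric(1), "z"),
      p_cond = vapply(cond, `[[`, numeric(1), "p"),
      flag = vapply(cond, `[[`, character(1), "flag"),
      p_gbj = cb$p_gbj, class = cb$class)
  }
  data.table::rbindlist(rows)
}
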