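# Discovery rules: Bonferroni thresholds, dual-reference consensus calls,
# GWAS-window lookups, summary counts.

#' Family-wise Bonferroni threshold over genes and traits
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_genes,n_traits Positive counts of candidate genes and traits.
#' @return `alpha / n_genes / n_traits`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 22694, 211)  # ~1.04e-8
bonferroni_threshold <- function(alpha, n_genes, n_traits) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(n_genes >= 1 && n_traits >= 1, "counts must be positive")
  alpha / n_genes / n_traits
}

#' Dual-reference consensus calls
#'
#' A gene-trait pair is called when it is (1) significant in both reference
#' versions, or (2) significant in one version while at least one
#' neighbouring gene — any gene whose `[start - window, end + window]`
#' interval overlaps the focal gene's body (1-based inclusive; equivalently,
#' gene bodies within `window_bp` of each other on the same chromosome) — is
#' significant for the same trait in the other version. Symmetric in the two
#' versions.
#'
#' @param results_v1,results_v2 Tables with `gene_id, trait, p`.
#' @param annotation Gene table (`gene_id, chr, start, end`).
#' @param threshold Significance threshold (p < threshold).
#' @param window_bp Neighbourhood window (default 1e6).
#' @return A `data.table` with one row per gene x trait seen in either
#'   version: `gene_id, trait, significant_v1, significant_v2,
#'   neighbor_rescue, final_call`. Genes absent from the annotation are
#'   excluded and logged in `attr(, "excluded")`.
#' @export
consensus_calls <- function(results_v1, results_v2, annotation, threshold,
                            window_bp = 1e6) {
  r1 <- data.table::as.data.table(results_v1)
  r2 <- data.table::as.data.table(results_v2)
  ann <- data.table::as.data.table(annotation)
  pairs <- unique(rbind(r1[, c("gene_id", "trait")],
                        r2[, c("gene_id", "trait")]))
  known <- pairs$gene_id %in% ann$gene_id
  excluded <- unique(pairs$gene_id[!known])
  pairs <- pairs[known, ]
  sig_of <- function(r) {
    key <- paste(r$gene_id, r$trait, sep = "\r")
    stats::setNames(r$p < threshold, key)
  }
  s1 <- sig_of(r1); s2 <- sig_of(r2)
  key <- paste(pairs$gene_id, pairs$trait, sep = "\r")
  sv1 <- !is.na(s1[key]) & s1[key]
  sv2 <- !is.na(s2[key]) & s2[key]
  # neighbour lookup: padded-interval overlap on the same chromosome
  ai <- match(pairs$gene_id, ann$gene_id)
  neighbors <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- ai[i]
    hit <- ann$chr == ann$chr[g] &
      ann$start - window_bp <= ann$end[g] &
      ann$end + window_bp >= ann$start[g] &
      ann$gene_id != ann$gene_id[g]
    ann$gene_id[hit]
  })
  rescue <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (sv1[i] == sv2[i]) next      # rescue only applies to one-sided hits
    nb <- neighbors[[i]]
    if (!length(nb)) next
    nbkey <- paste(nb, pairs$trait[i], sep = "\r")
    other <- if (sv1[i]) s2 else s1
    rescue[i] <- any(!is.na(other[nbkey]) & other[nbkey])
  }
  out <- data.table::data.table(
    gene_id = pairs$gene_id, trait = pairs$trait,
    significant_v1 = unname(sv1), significant_v2 = unname(sv2),
    neighbor_rescue = rescue,
    final_call = (unname(sv1) & unname(sv2)) |
      ((unname(sv1) | unname(sv2)) & rescue))
  attr(out, "excluded") <- excluded
  out
}

#' Most significant GWAS variant in a gene's window
#'
#' Scans SNPs on the gene's chromosome with position in
#' `[start - window_bp, end + window_bp]` and returns the minimum p-value,
#' the variant attaining it, and a flag for windows whose best signal is
#' weaker than `weak_cut` (the convention for TWAS hits without nearby GWAS
#' support).
#'
#' @param gene_id Focal gene id.
#' @param annotation Gene table.
#' @param gwas GWAS summary table (`snp, chr, pos, p`).
#' @param window_bp Window half-width (default 1e6).
#' @param weak_cut Weak-signal cut (default 1e-6).
#' @return List: `min_p`, `variant`, `weak_flag`; for an empty window,
#'   `min_p = NA`, `variant = NA`, `weak_flag = "no_snp"`.
#' @export
min_gwas_p_in_window <- function(gene_id, annotation, gwas,
                                 window_bp = 1e6, weak_cut = 1e-6) {
  g <- annotation[annotation$gene_id == gene_id, ]
  assert_that(nrow(g) == 1L, "gene not found in annotation")
  inwin <- gwas$chr == g$chr & gwas$pos >= g$start - window_bp &
    gwas$pos <= g$end + window_bp
  if (!any(inwin)) {
    return(list(min_p = NA_real_, variant = NA_character_,
                weak_flag = "no_snp"))
  }
  sub <- gwas[inwin, ]
  i <- which.min(sub$p)
  list(min_p = sub$p[i], variant = sub$snp[i],
       weak_flag = sub$p[i] > weak_cut)
}

#' Summarize consensus calls
#'
#' Deduplicates gene x trait rows, then tabulates called associations.
#'
#' @param calls Output of [consensus_calls()] (or any table with
#'   `gene_id, trait, final_call`).
#' @return List of counts: `n_associations`, `n_genes`, `n_traits`, and
#'   `genes_gt2`, `genes_gt5`, `genes_ge10` (genes with more than 2, more
#'   than 5, at least 10 called associations).
#' @export
summarize_discovery <- function(calls) {
  calls <- unique(data.table::as.data.table(calls),
                  by = c("gene_id", "trait"))
  hit <- calls[calls$final_call == TRUE, ]
  per_gene <- table(hit$gene_id)
  list(n_associations = nrow(hit),
       n_genes = length(unique(hit$gene_id)),
       n_traits = length(unique(hit$trait)),
       genes_gt2 = sum(per_gene > 2),
       genes_gt5 = sum(per_gene > 5),
       genes_ge10 = sum(per_gene >= 10))
}
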