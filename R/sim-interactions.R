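# Simulated promoter-anchored chromatin interactions.

#' Simulate chromatin-interaction data with a planted active gene set
#'
#' Per-gene interaction counts are negative binomial; genes in
#' `active_genes` get a mean shift, giving the enrichment test a
#' controllable truth. Each counted interaction is emitted as an interval
#' pair whose first anchor lies inside the gene body and whose confidence
#' score exceeds `score_cut`; additional sub-threshold interactions are
#' sprinkled in as negatives.
#'
#' @param annotation Gene table (`gene_id, chr, start, end`).
#' @param active_genes Character vector of gene ids receiving the mean shift.
#' @param mu0 Baseline negative-binomial mean (default 2).
#' @param shift Additive mean shift for active genes (default 2).
#' @param size Negative-binomial dispersion parameter (default 5).
#' @param score_cut Score threshold separating counted from sub-threshold
#'   interactions (default 5, matching the counting rule).
#' @return List with `interactions` (a `data.table`
#'   `chrA, startA, endA, chrB, startB, endB, score`) and `counts`
#'   (`gene_id, count` of score-passing interactions).
#' @export
simulate_interactions <- function(annotation, active_genes = character(),
                                  mu0 = 2, shift = 2, size = 5,
                                  score_cut = 5) {
  rows <- vector("list", nrow(annotation))
  counts <- integer(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    mu <- mu0 + shift * (g$gene_id %in% active_genes)
    k <- rnbinom(1L, size = size, mu = mu)
    counts[i] <- k
    k_sub <- rpois(1L, 1)
    m <- k + k_sub
    if (m == 0L) next
    sa <- as.integer(round(runif(m, g$start, max(g$start, g$end - 5000))))
    # distal anchors land beyond the simulated gene map so each interaction
    # overlaps exactly one gene
    sb <- as.integer(round(runif(m, 6e7, 9e7)))
    rows[[i]] <- data.table::data.table(
      chrA = g$chr, startA = sa, endA = sa + 4999L,
      chrB = g$chr, startB = sb, endB = sb + 4999L,
      score = c(runif(k, score_cut + 0.01, score_cut + 10),
                runif(k_sub, 0, score_cut)))
  }
  list(interactions = data.table::rbindlist(rows),
       counts = data.table::data.table(gene_id = annotation$gene_id,
                                       count = counts))
}
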