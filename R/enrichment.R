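# Chromatin-interaction enrichment: interval-overlap counting and a
# tie-aware Wilcoxon rank-sum test.

#' Count score-passing interactions per gene
#'
#' An interaction contributes to a gene when its confidence score strictly
#' exceeds `score_cut` and either anchor interval overlaps the gene body
#' (1-based inclusive; exact abutment counts). An interaction overlapping a
#' gene with both anchors is counted once. Malformed rows (non-positive
#' coordinates or start > end) are dropped and logged.
#'
#' @param interactions Table with columns
#'   `chrA, startA, endA, chrB, startB, endB, score`.
#' @param annotation Gene table (`gene_id, chr, start, end`).
#' @param score_cut Strict score threshold (default 5).
#' @return A `data.table` `gene_id, count` covering every annotated gene,
#'   with dropped rows in `attr(, "dropped")`.
#' @export
count_interactions <- function(interactions, annotation, score_cut = 5) {
  it <- data.table::as.data.table(interactions)
  bad <- !(it$startA <= it$endA & it$startB <= it$endB &
             it$startA > 0 & it$startB > 0)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) message(sum(bad), " malformed interaction rows dropped")
  dropped <- it[bad, ]
  it <- it[!bad & it$score > score_cut, ]
  counts <- integer(nrow(annotation))
  if (nrow(it) > 0L) {
    genes <- IRanges::IRanges(annotation$start, annotation$end)
    hitpairs <- list()
    for (side in c("A", "B")) {
      anch <- IRanges::IRanges(it[[paste0("start", side)]],
                               it[[paste0("end", side)]])
      for (ch in unique(annotation$chr)) {
        gi <- which(annotation$chr == ch)
        ii <- which(it[[paste0("chr", side)]] == ch)
        if (!length(gi) || !length(ii)) next
        ov <- IRanges::findOverlaps(anch[ii], genes[gi])
        if (length(ov)) {
          hitpairs[[length(hitpairs) + 1L]] <- cbind(
            ii[S4Vectors::queryHits(ov)], gi[S4Vectors::subjectHits(ov)])
        }
      }
    }
    if (length(hitpairs)) {
      hp <- unique(do.call(rbind, hitpairs))
      tab <- table(hp[, 2L])
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  out <- data.table::data.table(gene_id = annotation$gene_id, count = counts)
  attr(out, "dropped") <- dropped
  out
}

# Tie-aware rank-sum permutation enumeration over all group assignments.
#' @noRd
ranksum_exact <- function(ranks, n1, w_obs, alternative) {
  n <- length(ranks)
  combos <- utils::combn(n, n1)
  W <- colSums(matrix(ranks[combos], nrow = n1))
  eps <- 1e-9
  if (alternative == "greater") {
    mean(W >= w_obs - eps)
  } else {
    mu <- n1 * (n + 1) / 2
    mean(abs(W - mu) >= abs(w_obs - mu) - eps)
  }
}

#' Wilcoxon rank-sum enrichment test
#'
#' Tests whether interaction counts of the significant gene set exceed those
#' of the remaining genes. When both groups have at most 12 members the
#' p-value is computed by exact enumeration of all group assignments on the
#' tie-averaged ranks; otherwise the normal approximation with tie and
#' continuity correction is used. The hypothesis is directional, so the
#' default alternative is `"greater"`.
#'
#' @param counts Table `gene_id, count` ([count_interactions()]).
#' @param significant_set Character vector of significant gene ids.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exact_max Group-size bound for exact enumeration (default 12).
#' @return List: `statistic` (Mann-Whitney U of the significant group),
#'   `p`, `method`.
#' @export
rank_sum_enrichment <- function(counts, significant_set,
                                alternative = c("greater", "two.sided"),
                                exact_max = 12L) {
  alternative <- match.arg(alternative)
  sig <- counts$gene_id %in% significant_set
  assert_that(any(sig) && any(!sig),
              "both significant and non-significant groups must be non-empty")
  x <- counts$count
  n1 <- sum(sig); n2 <- sum(!sig); n <- n1 + n2
  ranks <- rank(x)
  W <- sum(ranks[sig])
  U <- W - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- ranksum_exact(ranks, n1, W, alternative)
    method <- "exact"
  } else {
    ties <- table(x)
    muW <- n1 * (n + 1) / 2
    s2 <- n1 * n2 * (n + 1) / 12 -
      n1 * n2 * sum(ties^3 - ties) / (12 * n * (n - 1))
    if (s2 <= 0) {
      p <- 1
    } else if (alternative == "greater") {
      p <- pnorm((W - muW - 0.5) / sqrt(s2), lower.tail = FALSE)
    } else {
      p <- 2 * pnorm((abs(W - muW) - 0.5) / sqrt(s2), lower.tail = FALSE)
      p <- min(p, 1)
    }
    method <- "normal"
  }
  list(statistic = U, p = p, method = method)
}
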