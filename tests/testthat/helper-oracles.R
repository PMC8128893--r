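# Independent oracles: deliberately naive re-implementations used only to
# check package results. None of them share code with the package internals.

# Classical Berk-Jones statistic by direct enumeration of order statistics:
# max over k <= ceiling(d/2) with k/d > p_k of the binomial log-GLR
# d * KL(k/d || p_k).
oracle_bj <- function(z) {
  d <- length(z)
  a <- sort(abs(z), decreasing = TRUE)
  best <- 0
  for (k in seq_len(ceiling(d / 2))) {
    pk <- 2 * pnorm(-a[k])
    if (k / d <= pk) next
    kl <- (k / d) * log((k / d) / pk)
    if (k < d) kl <- kl + (1 - k / d) * log((1 - k / d) / (1 - pk))
    best <- max(best, d * kl)
  }
  best
}

# Individual-level OLS z (t-statistic) of y on a single predictor x,
# optionally with extra covariates, via lm().
oracle_ols_z <- function(y, x, covars = NULL) {
  df <- if (is.null(covars)) data.frame(y = y, x = x) else
    data.frame(y = y, x = x, covars)
  fit <- summary(lm(y ~ ., data = df))
  fit$coefficients["x", "t value"]
}

# Brute-force interval overlap count: score-passing interactions with either
# anchor overlapping the gene body (1-based inclusive).
oracle_interaction_counts <- function(interactions, annotation,
                                      score_cut = 5) {
  sapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    hit <- 0L
    for (j in seq_len(nrow(interactions))) {
      it <- interactions[j, ]
      if (!(it$score > score_cut)) next
      ovA <- it$chrA == g$chr && it$startA <= g$end && it$endA >= g$start
      ovB <- it$chrB == g$chr && it$startB <= g$end && it$endB >= g$start
      if (ovA || ovB) hit <- hit + 1L
    }
    hit
  })
}

# Naive full scan for the smallest GWAS p in a gene window.
oracle_min_p <- function(gene_id, annotation, gwas, window_bp = 1e6) {
  g <- annotation[annotation$gene_id == gene_id, ]
  best_p <- Inf
  best_snp <- NA_character_
  for (j in seq_len(nrow(gwas))) {
    if (gwas$chr[j] != g$chr) next
    if (gwas$pos[j] < g$start - window_bp) next
    if (gwas$pos[j] > g$end + window_bp) next
    if (gwas$p[j] < best_p) {
      best_p <- gwas$p[j]
      best_snp <- gwas$snp[j]
    }
  }
  if (is.infinite(best_p)) list(min_p = NA_real_, variant = NA_character_)
  else list(min_p = best_p, variant = best_snp)
}

# Exhaustive consensus-rule oracle: for every gene x trait, apply the
# dual-version rule by scanning all other genes for the neighbour clause.
oracle_consensus <- function(results_v1, results_v2, annotation, threshold,
                             window_bp = 1e6) {
  sig <- function(r, g, tr) {
    i <- which(r$gene_id == g & r$trait == tr)
    length(i) > 0 && r$p[i] < threshold
  }
  pairs <- unique(rbind(results_v1[, c("gene_id", "trait")],
                        results_v2[, c("gene_id", "trait")]))
  pairs <- pairs[pairs$gene_id %in% annotation$gene_id, ]
  out <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[i]; tr <- pairs$trait[i]
    s1 <- sig(results_v1, g, tr); s2 <- sig(results_v2, g, tr)
    if (s1 && s2) { out[i] <- TRUE; next }
    if (!s1 && !s2) next
    ga <- annotation[annotation$gene_id == g, ]
    for (j in seq_len(nrow(annotation))) {
      nb <- annotation[j, ]
      if (nb$gene_id == g || nb$chr != ga$chr) next
      if (nb$start - window_bp > ga$end || nb$end + window_bp < ga$start) next
      hit <- if (s1) sig(results_v2, nb$gene_id, tr) else
        sig(results_v1, nb$gene_id, tr)
      if (hit) { out[i] <- TRUE; break }
    }
  }
  data.frame(gene_id = pairs$gene_id, trait = pairs$trait, final_call = out)
}

standardize_held_out <- function(X) {
  mu <- colMeans(X)
  sd0 <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sd0[sd0 == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sd0, "/")
}

# Small default study shared by several test files (kept deliberately tiny).
tiny_study <- function(seed = 11, ...) {
  defaults <- list(n_ref = 400, n_gwas = 1500, n_train = 500, n_test = 300,
                   n_genes = 6, snps_per_gene = 8, n_tissues = 4,
                   seed = seed)
  cfg <- do.call(sim_config, utils::modifyList(defaults, list(...)))
  simulate_study(cfg)
}
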