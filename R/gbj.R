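# Cross-tissue combination: generalized Berk-Jones over correlated
# tissue-level z-statistics, with Monte-Carlo p-values.

#' Cross-tissue covariance of single-tissue TWAS statistics
#'
#' Under the null, the tissue-level statistics of one gene are jointly normal
#' with correlations
#' \deqn{\Sigma_{ts} = \frac{w_t' D w_s}{\sqrt{(w_t' D w_t)(w_s' D w_s)}},}
#' the correlation of the imputed expression values under the LD reference.
#'
#' @param W SNP x tissue matrix of aligned weights (shared SNP set).
#' @param D SNP correlation matrix.
#' @return List: `sigma` (tissue correlation matrix, clipped to `[-1, 1]`
#'   and projected to the nearest PSD matrix if needed), `degenerate`
#'   (TRUE when all off-diagonals are ~1), `projected`.
#' @export
tissue_covariance <- function(W, D) {
  W <- as.matrix(W)
  assert_that(ncol(W) >= 2L, "need at least two tissues")
  Q <- crossprod(W, D %*% W)
  s <- sqrt(diag(Q))
  assert_that(all(s > 0), "a tissue has zero imputed-expression variance")
  S <- Q / tcrossprod(s)
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  projected <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    projected <- TRUE
    v <- pmax(ev$values, 0)
    S <- ev$vectors %*% (v * t(ev$vectors))
    dd <- sqrt(diag(S))
    S <- S / tcrossprod(dd)
    diag(S) <- 1
  }
  off <- S[upper.tri(S)]
  list(sigma = S, degenerate = length(off) > 0 && all(off > 0.999),
       projected = projected)
}

#' Precompute correlation corrections for a GBJ null covariance
#'
#' Tabulates, on a threshold grid, the pairwise bivariate-normal
#' orthant-probability correction
#' \eqn{\sum_{i<j} [P(|Z_i| \ge t, |Z_j| \ge t) - p(t)^2]} implied by
#' `sigma`, so that repeated statistic evaluations (Monte-Carlo draws) reuse
#' it by interpolation.
#'
#' @param sigma Tissue correlation matrix.
#' @return An object of class `gbj_prep`.
#' @export
gbj_prepare <- function(sigma) {
  sigma <- as.matrix(sigma)
  d <- nrow(sigma)
  tgrid <- seq(0, 9, length.out = 241L)
  # dimensionless variance inflation sigma_k^2 / (d p (1 - p)); stored as a
  # ratio so extreme thresholds (p underflowing) stay well-defined — the
  # pairwise correction vanishes relative to the binomial variance as t
  # grows, so the ratio tends to 1 in the tails
  ratio <- rep(1, length(tgrid))
  if (d > 1L) {
    rs <- sigma[upper.tri(sigma)]
    p <- 2 * pnorm(tgrid, lower.tail = FALSE)
    corr <- numeric(length(tgrid))
    for (r in rs) corr <- corr + orthant_abs2(tgrid, r) - p^2
    denom <- d * p * (1 - p)
    ok <- denom > 1e-280
    ratio[ok] <- pmax(1 + 2 * corr[ok] / denom[ok], 1e-3)
  }
  structure(list(d = d, tgrid = tgrid, ratio = ratio, sigma = sigma),
            class = "gbj_prep")
}

# Vectorized statistic on a matrix of z-vectors (rows = draws).
#' @noRd
gbj_stat_matrix <- function(Z, prep) {
  d <- prep$d
  A <- abs(Z)
  if (d > 1L) {
    # row-wise descending sort via one radix order (fast for many draws)
    o <- order(row(A), -A)
    A <- matrix(A[o], ncol = d, byrow = TRUE)
  }
  kmax <- as.integer(ceiling(d / 2))
  stat <- numeric(nrow(A))
  for (k in seq_len(kmax)) {
    tk <- A[, k]
    pk <- pmin(pmax(2 * pnorm(tk, lower.tail = FALSE), 1e-300), 1 - 1e-16)
    elig <- which(k / d > pk)
    if (!length(elig)) next
    pe <- pk[elig]
    bj <- k * log(k / (d * pe)) +
      if (d - k > 0) (d - k) * log((d - k) / (d * (1 - pe))) else 0
    infl <- stats::approx(prep$tgrid, prep$ratio, tk[elig], rule = 2)$y
    stat[elig] <- pmax(stat[elig], bj / infl)
  }
  stat
}

#' Generalized Berk-Jones statistic
#'
#' Sorts `|z|` in decreasing order; for each `k <= ceiling(d/2)` whose
#' empirical exceedance fraction `k/d` exceeds the two-sided tail probability
#' `p_k = 2 * pnorm(-|z|_(k))`, computes the Berk-Jones binomial log
#' generalized-likelihood ratio for the exceedance count and rescales it by
#' the variance ratio `d p_k (1 - p_k) / sigma_k^2`, where `sigma_k^2`
#' inflates the binomial variance with pairwise bivariate-normal orthant
#' probabilities under `sigma`. The statistic is the maximum over eligible
#' `k` (0 if none); with `sigma = I` it equals the classical Berk-Jones
#' statistic.
#'
#' @param z_vec Tissue-level z-statistics (length d >= 1).
#' @param sigma Tissue correlation matrix (ignored if `prep` given).
#' @param prep Optional precomputed [gbj_prepare()] object.
#' @return Non-negative scalar statistic.
#' @export
gbj_statistic <- function(z_vec, sigma = NULL, prep = NULL) {
  d <- length(z_vec)
  assert_that(d >= 1L, "empty z vector")
  if (is.null(prep)) {
    if (is.null(sigma)) sigma <- diag(d)
    prep <- gbj_prepare(sigma)
  }
  assert_that(prep$d == d, "sigma dimension does not match z vector")
  gbj_stat_matrix(matrix(z_vec, nrow = 1L), prep)
}

#' Monte-Carlo p-value for the generalized Berk-Jones test
#'
#' Draws `B` null vectors from `MVN(0, sigma)` and applies the add-one
#' estimator `p = (1 + #{stat_null >= stat_obs}) / (B + 1)`; bit-reproducible
#' given `seed`. The optional analytic boundary-crossing computation is not
#' implemented; Monte Carlo is the reference method.
#'
#' @param z_vec Observed tissue-level z-statistics.
#' @param sigma Tissue correlation matrix.
#' @param method Only `"mc"` is available.
#' @param B Number of Monte-Carlo draws (>= 1000 recommended; smaller values
#'   warn).
#' @param seed Integer seed.
#' @param prep Optional [gbj_prepare()] object for `sigma`.
#' @return List: `stat`, `p`, `B`, `seed`.
#' @export
gbj_pvalue <- function(z_vec, sigma, method = c("mc", "analytic"),
                       B = 2000L, seed = 1L, prep = NULL) {
  method <- match.arg(method)
  if (method == "analytic") {
    stop("analytic GBJ p-values are not implemented; use method = 'mc'",
         call. = FALSE)
  }
  if (B < 1000L) warning("B < 1000: Monte-Carlo p-value will be coarse")
  d <- length(z_vec)
  sigma <- as.matrix(sigma)
  assert_that(nrow(sigma) == d && isTRUE(all.equal(sigma, t(sigma))),
              "invalid sigma")
  if (is.null(prep)) prep <- gbj_prepare(sigma)
  obs <- gbj_stat_matrix(matrix(z_vec, nrow = 1L), prep)
  # eigen square root tolerates the degenerate (rank-deficient) case
  ev <- eigen(sigma, symmetric = TRUE)
  R <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  old <- .Random.seed_save()
  set.seed(seed)
  Z <- matrix(rnorm(B * d), B, d) %*% R
  .Random.seed_restore(old)
  nulls <- gbj_stat_matrix(Z, prep)
  list(stat = obs, p = (1 + sum(nulls >= obs)) / (B + 1),
       B = as.integer(B), seed = as.integer(seed))
}

#' Combine single-tissue results for one gene across panels
#'
#' Computes the tissue covariance from the aligned weights and LD, collapses
#' effectively duplicated tissues (pairwise correlation > `collapse_tol`,
#' which would make the null singular), and returns the GBJ statistic and
#' Monte-Carlo p-value. `tissues` restricts to a subset (e.g. brain-only
#' mode); running on a subset equals running the all-tissue mode on that
#' subset.
#'
#' @param z Named (by tissue) vector of single-tissue z-statistics.
#' @param W SNP x tissue aligned weight matrix (columns named like `z`).
#' @param D SNP correlation matrix.
#' @param tissues Optional character subset of tissues.
#' @param B,seed Monte-Carlo controls.
#' @param collapse_tol Correlation above which tissues are collapsed
#'   (default 0.999).
#' @return List: `stat`, `p`, `n_tissues` (after collapsing), `sigma`,
#'   `B`, `seed`, `collapsed` (dropped tissue names).
#' @export
combine_tissues <- function(z, W, D, tissues = NULL, B = 2000L, seed = 1L,
                            collapse_tol = 0.999) {
  if (!is.null(tissues)) {
    z <- z[tissues]
    W <- W[, tissues, drop = FALSE]
  }
  if (length(z) == 1L) {
    pv <- gbj_pvalue(z, diag(1), B = B, seed = seed)
    return(list(stat = pv$stat, p = pv$p, n_tissues = 1L,
                sigma = diag(1), B = pv$B, seed = pv$seed,
                collapsed = character()))
  }
  tc <- tissue_covariance(W, D)
  S <- tc$sigma
  keep <- rep(TRUE, length(z))
  for (i in seq_along(z)) {
    if (!keep[i]) next
    dup <- which(keep & seq_along(z) > i & S[i, ] > collapse_tol)
    keep[dup] <- FALSE
  }
  zk <- z[keep]
  Sk <- S[keep, keep, drop = FALSE]
  pv <- if (length(zk) == 1L) {
    gbj_pvalue(zk, diag(1), B = B, seed = seed)
  } else {
    gbj_pvalue(zk, Sk, B = B, seed = seed)
  }
  list(stat = pv$stat, p = pv$p, n_tissues = sum(keep), sigma = Sk,
       B = pv$B, seed = pv$seed, collapsed = names(z)[!keep])
}
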