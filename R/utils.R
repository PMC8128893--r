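# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Column standardization with population (1/n) variance so that
# crossprod(Xs)/n has an exactly unit diagonal. Zero-variance columns are
# reported so callers can drop them.
#' @noRd
standardize_columns <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sdv <- sqrt(colMeans(Xc^2))
  keep <- sdv > 0
  Xs <- Xc
  Xs[, keep] <- sweep(Xc[, keep, drop = FALSE], 2L, sdv[keep], "/")
  list(X = Xs[, keep, drop = FALSE], keep = keep, mean = mu, sd = sdv)
}

# Gauss-Legendre nodes/weights on [0, 1], cached at package load time.
.gl32 <- local({
  # 32-point rule computed from the Golub-Welsch eigenproblem.
  k <- seq_len(31L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, 32L, 32L)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (rev(e$values) + 1) / 2,
       w = rev(2 * e$vectors[1L, ]^2) / 2)
})

# Bivariate standard normal CDF P(Z1 <= h, Z2 <= k) at correlation r,
# via Plackett's identity dPhi2/dr = phi2(h, k; r). Vectorized over h, k
# (equal length); scalar r in (-1, 1).
#' @noRd
pbinorm <- function(h, k, r) {
  base <- pnorm(h) * pnorm(k)
  if (r == 0) return(base)
  u <- .gl32$x * r                      # nodes on [0, r] (signed)
  w <- .gl32$w * r
  hk <- h * k
  h2k2 <- h^2 + k^2
  acc <- 0
  for (i in seq_along(u)) {
    ui <- u[i]
    dens <- exp(-(h2k2 - 2 * ui * hk) / (2 * (1 - ui^2))) /
      (2 * pi * sqrt(1 - ui^2))
    acc <- acc + w[i] * dens
  }
  base + acc
}

# P(|Z1| >= t, |Z2| >= t) for bivariate standard normal with correlation r.
# Vectorized over t.
#' @noRd
orthant_abs2 <- function(t, r) {
  # Upper-quadrant mass L(t, t; rho) = P(Z1 > t, Z2 > t)
  upper <- function(rho) {
    pnorm(t, lower.tail = FALSE)^2 +
      (pbinorm(t, t, rho) - pnorm(t)^2)
  }
  # |Z| exceedance decomposes into the two symmetric quadrant pairs
  2 * (upper(r) + upper(-r))
}

# Residualize y on a covariate matrix (intercept always included).
#' @noRd
residualize <- function(y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    return(y - mean(y))
  }
  Q <- qr(cbind(1, as.matrix(covariates)))
  qr.resid(Q, y)
}

# Marginal OLS t-statistics of y (already residualized) on each column of X.
#' @noRd
marginal_z <- function(X, y) {
  n <- length(y)
  sx <- standardize_columns(X)
  ys <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  r <- rep(NA_real_, ncol(X))
  r[sx$keep] <- as.vector(crossprod(sx$X, ys)) / n
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  r * sqrt((n - 2) / (1 - r^2))
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
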