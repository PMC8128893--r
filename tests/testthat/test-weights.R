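# Sparse-group-lasso weight training: closed-form and glmnet oracles,
# objective monotonicity, group-sparsity pattern, cross-validation.

make_orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- sweep(Z, 2, colMeans(Z))          # orthogonal to the intercept
  qr.Q(qr(Z)) * sqrt(n)                  # population-scale unit columns
}

test_that("extreme penalties shrink every weight to zero", {
  set.seed(1)
  X <- matrix(rbinom(200 * 6, 2, 0.3), 200, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  Y <- matrix(rnorm(200 * 3), 200, 3)
  fit <- train_cross_tissue(Y, X, lambda_lasso = 50, lambda_group = 50)
  expect_true(all(fit$beta == 0))
  expect_true(fit$converged)
  expect_error(train_cross_tissue(Y, X, lambda_lasso = -1), "non-negative")
})

test_that("orthonormal single-tissue case equals soft-thresholded OLS", {
  n <- 400; p <- 8
  Xs <- make_orthonormal_design(n, p, seed = 2)
  colnames(Xs) <- paste0("s", 1:p)
  beta <- c(2, -1.5, 0, 0, 1, 0, 0, 0)
  set.seed(3)
  y <- Xs %*% beta + rnorm(n)
  l1 <- 0.3
  fit <- train_cross_tissue(matrix(y), Xs, lambda_lasso = l1,
                            lambda_group = 0, tol = 1e-10)
  ys <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  ols <- as.vector(crossprod(Xs, ys) / n)
  oracle <- sign(ols) * pmax(abs(ols) - l1, 0)
  expect_lt(sqrt(mean((fit$beta[, 1] - oracle)^2)), 1e-4)
})

test_that("single-tissue lasso matches glmnet within 1e-4 RMSE", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  n <- 300; p <- 12
  X <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.5)), n, p, byrow = TRUE,
              dimnames = list(NULL, paste0("s", 1:p)))
  y <- X[, 2] * 0.5 - X[, 7] * 0.3 + rnorm(n)
  sx <- scale(X) * sqrt(n / (n - 1))     # population-scale standardization
  ys <- as.vector(scale(y)) * sqrt(n / (n - 1))
  l1 <- 0.08
  fit <- train_cross_tissue(matrix(y), X, lambda_lasso = l1,
                            lambda_group = 0, tol = 1e-12,
                            max_iter = 5000)
  gn <- glmnet::glmnet(sx, ys, lambda = l1, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_lt(sqrt(mean((fit$beta[, 1] - as.vector(gn$beta))^2)), 1e-4)
  expect_lt(fit$kkt, 1e-6)
})

test_that("objective decreases monotonically on random fixtures", {
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rbinom(150 * 10, 2, 0.3), 150, 10,
                dimnames = list(NULL, paste0("s", 1:10)))
    Y <- matrix(rnorm(150 * 4), 150, 4)
    Y[, 1] <- Y[, 1] + 0.4 * X[, 3]
    fit <- train_cross_tissue(Y, X, lambda_lasso = 0.05,
                              lambda_group = 0.05)
    expect_true(all(diff(fit$objective) <= 1e-10))
    expect_lt(fit$kkt, 10 * 1e-7 + 1e-8)
  }
})

test_that("group penalty yields all-zero or multi-tissue SNP rows", {
  sim <- tiny_study(seed = 51, cis_h2 = 0.4, cross_tissue_cor = 0.9)
  i <- which(sim$geno_ref$snps$gene_id == "GENE001")
  E <- vapply(sim$expression, function(m) m[, "GENE001"],
              numeric(nrow(sim$geno_ref$X)))
  fit <- train_cross_tissue(E, sim$geno_ref$X[, i], lambda_lasso = 0.01,
                            lambda_group = 0.15)
  nz_per_row <- rowSums(fit$beta != 0)
  expect_true(all(nz_per_row == 0 | nz_per_row >= 2))
})

test_that("causal eQTLs are recovered at CV-chosen penalties", {
  cfg <- sim_config(n_ref = 800, n_genes = 1, snps_per_gene = 10,
                    n_tissues = 5, cis_h2 = 0.4, cross_tissue_cor = 0.9,
                    n_causal_eqtl_per_gene = 3, seed = 61)
  sim <- simulate_study(cfg, cohorts = character())
  i <- which(sim$geno_ref$snps$gene_id == "GENE001")
  E <- vapply(sim$expression, function(m) m[, "GENE001"],
              numeric(cfg$n_ref))
  grid <- expand.grid(lambda_lasso = c(0.01, 0.05, 0.1),
                      lambda_group = c(0.01, 0.05))
  cv <- cross_validate_penalties(E, sim$geno_ref$X[, i], grid,
                                 n_folds = 3, seed = 2)
  fit <- train_cross_tissue(E, sim$geno_ref$X[, i],
                            cv$lambda_lasso, cv$lambda_group)
  causal <- match(sim$truth$causal[["GENE001"]],
                  sim$geno_ref$snps$snp[i])
  hits <- rowSums(fit$beta[causal, , drop = FALSE] != 0) >= cfg$n_tissues / 2
  expect_gte(sum(hits), 2)
})

test_that("cross-validation behaves at the extremes", {
  # degenerate one-point grid
  sim <- tiny_study(seed = 71)
  i <- which(sim$geno_ref$snps$gene_id == "GENE002")
  E <- vapply(sim$expression, function(m) m[, "GENE002"],
              numeric(nrow(sim$geno_ref$X)))
  one <- data.frame(lambda_lasso = 0.07, lambda_group = 0.02)
  cv1 <- cross_validate_penalties(E, sim$geno_ref$X[, i], one, 3, seed = 1)
  expect_equal(cv1$lambda_lasso, 0.07)
  expect_equal(cv1$lambda_group, 0.02)
  expect_error(cross_validate_penalties(E, sim$geno_ref$X[, i],
                                        one[0, ], 3), "empty")
  # null expression: chosen model predicts nothing out of sample
  sim0 <- tiny_study(seed = 72, cis_h2 = 0, mediated_h2 = 0)
  i0 <- which(sim0$geno_ref$snps$gene_id == "GENE001")
  E0 <- vapply(sim0$expression, function(m) m[, "GENE001"],
               numeric(nrow(sim0$geno_ref$X)))
  grid <- expand.grid(lambda_lasso = c(0.02, 0.1),
                      lambda_group = c(0.02, 0.1))
  cv0 <- cross_validate_penalties(E0, sim0$geno_ref$X[, i0], grid, 3,
                                  seed = 3)
  half <- seq_len(nrow(E0) / 2)
  fit0 <- train_cross_tissue(E0[half, ], sim0$geno_ref$X[half, i0],
                             cv0$lambda_lasso, cv0$lambda_group)
  pred <- standardize_held_out(sim0$geno_ref$X[-half, i0]) %*% fit0$beta
  r2 <- mean(vapply(seq_len(ncol(E0)), function(t) {
    if (all(pred[, t] == 0)) 0 else cor(pred[, t], E0[-half, t])^2
  }, numeric(1)))
  expect_lte(r2, 0.02)
  # strong signal with a lambda = 0 grid point: the chosen point is never
  # worse than the unpenalized one
  simS <- tiny_study(seed = 73, cis_h2 = 0.6)
  iS <- which(simS$geno_ref$snps$gene_id == "GENE001")
  ES <- vapply(simS$expression, function(m) m[, "GENE001"],
               numeric(nrow(simS$geno_ref$X)))
  gridS <- data.frame(lambda_lasso = c(0, 0.05, 0.15),
                      lambda_group = c(0, 0.05, 0.15))
  cvS <- cross_validate_penalties(ES, simS$geno_ref$X[, iS], gridS, 3,
                                  seed = 4)
  tab <- cvS$cv
  chosen <- tab$cv_error[tab$lambda_lasso == cvS$lambda_lasso &
                           tab$lambda_group == cvS$lambda_group]
  unpen <- tab$cv_error[tab$lambda_lasso == 0 & tab$lambda_group == 0]
  expect_lte(chosen, unpen)
})

test_that("trained and oracle panels satisfy the WeightPanel invariants", {
  sim <- tiny_study(seed = 81, cis_h2 = 0.4)
  panel <- train_weight_panel(sim, 0.05, 0.05)
  expect_silent(validate_weight_panel(panel, sim$geno_ref$snps$snp))
  expect_gt(nrow(panel), 0)
  bad <- rbind(panel, panel[1, ])
  expect_error(validate_weight_panel(bad), "duplicate")
})
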