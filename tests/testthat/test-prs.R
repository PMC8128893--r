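# Gene-based polygenic scores and incremental R^2 evaluation.

test_that("threshold grid is the canonical 17-value sequence", {
  g <- prs_threshold_grid()
  expect_length(g, 17)
  expect_true(all(diff(g) < 0))
  expect_equal(g[1], 1)
  expect_equal(g[17], 5e-8)
})

test_that("imputation reproduces standardized dosages for unit weights", {
  sim <- tiny_study(seed = 52)
  sp <- sim$geno_ref$snps
  one <- data.table::data.table(
    gene_id = "GENE001", tissue_id = "tissue01",
    snp_id = sp$snp[1], effect_allele = sp$a1[1], other_allele = sp$a2[1],
    weight = 1)
  E <- impute_expression(sim$geno_ref, one)
  x <- sim$geno_ref$X[, 1]
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(E[, "GENE001"], xs, tolerance = 1e-12)
  # swapped alleles flip the imputed value
  two <- data.table::copy(one)
  two$effect_allele <- sp$a2[1]; two$other_allele <- sp$a1[1]
  expect_equal(impute_expression(sim$geno_ref, two)[, 1], -xs,
               tolerance = 1e-12)
  # zero-variance dosage columns are excluded before standardization
  g0 <- sim$geno_ref
  g0$X[, 1] <- 1L
  E0 <- impute_expression(g0, one)
  expect_equal(ncol(E0), 0)
})

test_that("oracle-weight imputation approaches the cis heritability bound", {
  cfg <- sim_config(n_genes = 8, n_ref = 4000, cis_h2 = 0.4,
                    cross_tissue_cor = 1, seed = 53)
  sim <- simulate_study(cfg, cohorts = character())
  E <- impute_expression(sim$geno_ref, oracle_weight_panel(sim),
                         tissue = "tissue01")
  r <- vapply(colnames(E), function(g) {
    i <- which(sim$geno_ref$snps$gene_id == g)
    truth_g <- as.vector(scale(sim$geno_ref$X[, i]) %*%
                           sim$truth$effects[[g]][, 1])
    cor(E[, g], truth_g)
  }, numeric(1))
  expect_gt(min(r), 0.999)   # same weights, same genotypes
  expect_lt(abs(mean(vapply(colnames(E), function(g) {
    cor(E[, g], sim$expression[[1]][, g])^2
  }, numeric(1))) - 0.4), 0.05)
})

test_that("gene effect estimation recovers truth and is null-calibrated", {
  set.seed(54)
  n <- 400
  covars <- training_covariates(rnorm(n), rbinom(n, 1, 0.5))
  E <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("gA", "gB")))
  y <- 2 * E[, 1] + covars %*% c(0.1, 0, 0.2, 0, 0) + rnorm(n)
  eff <- train_gene_effects(as.vector(y), E, covars)
  ci <- eff$beta[1] + c(-3, 3) * eff$se[1]
  expect_gt(2, ci[1]); expect_lt(2, ci[2])
  expect_lt(eff$p[1], 1e-10)
  # covariate-only phenotype: coefficient near zero
  y0 <- as.vector(covars %*% c(0.3, 0, 0.2, 0, 0) + rnorm(n))
  eff0 <- train_gene_effects(y0, E, covars)
  expect_lt(abs(eff0$beta[2]), 3 * eff0$se[2] + 0.2)
  # null p-values uniform across replicates
  ps <- replicate(400, {
    yn <- rnorm(120)
    En <- matrix(rnorm(120), 120, 1, dimnames = list(NULL, "g"))
    train_gene_effects(yn, En, training_covariates(rnorm(120),
                                                   rbinom(120, 1, 0.5)))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("profiles follow the threshold grid and hand arithmetic", {
  eff <- data.table::data.table(gene_id = c("g1", "g2"),
                                beta = c(2, -1), se = 1, p = c(0.009, 0.3))
  E <- matrix(c(1, 0, 2, 1, -1, 0.5), 3, 2,
              dimnames = list(NULL, c("g1", "g2")))
  prof <- build_profiles(E, eff)
  expect_equal(ncol(prof), 17)
  # tau = 1 includes both genes: 2*E[,1] - E[,2]
  expect_equal(prof[, 1], 2 * E[, "g1"] - E[, "g2"], ignore_attr = TRUE)
  # tau = 0.01 keeps only g1
  expect_equal(prof[, "0.01"], 2 * E[, "g1"], ignore_attr = TRUE)
  # tau = 5e-8 keeps nothing: zero profile, flagged
  expect_true(all(prof[, 17] == 0))
  expect_true(attr(prof, "empty")[17])
  expect_false(attr(prof, "empty")[1])
})

test_that("incremental R^2 obeys nesting and collinearity identities", {
  set.seed(55)
  n <- 500
  cov2 <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  prs <- rnorm(n)
  y <- 0.3 * prs + cov2 %*% c(0.1, 0.1) + rnorm(n)
  profiles <- cbind(`1e+00` = prs, `5e-01` = rnorm(n), `1e-02` = rep(0, n))
  ev <- evaluate_incremental_r2(as.vector(y), profiles, cov2,
                                gwas_prs = rnorm(n))
  expect_true(all(ev$r2_twas >= -1e-10))
  expect_true(all(ev$r2_joint >= pmax(ev$r2_twas, ev$r2_gwas) - 1e-10))
  # zero profile -> increments exactly zero
  expect_equal(ev$r2_twas[3], 0)
  # GWAS PRS identical to the TWAS profile -> no gain from m3 to m4
  ev2 <- evaluate_incremental_r2(as.vector(y), profiles[, 1, drop = FALSE],
                                 cov2, gwas_prs = prs)
  expect_lt(abs(ev2$r2_twas_given_gwas[1]), 1e-10)
  expect_error(evaluate_incremental_r2(rep(1, n), profiles, cov2),
               "constant")
})

test_that("test-set leakage inflates the apparent increment", {
  cfg <- sim_config(n_genes = 10, n_ref = 500, n_train = 2000, n_test = 800,
                    cis_h2 = 0.5, mediated_h2 = 0.15, direct_h2 = 0,
                    seed = 56)
  sim <- simulate_study(cfg, cohorts = c("train", "test"))
  panel <- oracle_weight_panel(sim)
  Etr <- impute_expression(sim$geno_train, panel, tissue = "tissue01")
  Ete <- impute_expression(sim$geno_test, panel, tissue = "tissue01")
  ctr <- training_covariates(sim$train$covariates[, 1],
                             sim$train$covariates[, 2])
  cte_eval <- sim$test$covariates
  honest_eff <- train_gene_effects(sim$train$phenotype, Etr, ctr)
  leaky_eff <- train_gene_effects(
    sim$test$phenotype, Ete,
    training_covariates(cte_eval[, 1], cte_eval[, 2]))
  honest <- attr(evaluate_incremental_r2(
    sim$test$phenotype, build_profiles(Ete, honest_eff), cte_eval), "best")
  leaky <- attr(evaluate_incremental_r2(
    sim$test$phenotype, build_profiles(Ete, leaky_eff), cte_eval), "best")
  expect_lt(honest, leaky)
})

test_that("larger reference panels give better prediction", {
  sizes <- c(150, 400, 1200)
  inc <- vapply(seq_along(sizes), function(i) {
    mean(vapply(1:2, function(r) {
      cfg <- sim_config(n_ref = sizes[i], n_genes = 10, n_tissues = 3,
                        n_train = 3000, n_test = 800, cis_h2 = 0.3,
                        mediated_h2 = 0.15, direct_h2 = 0,
                        seed = 570 + 10 * i + r)
      sim <- simulate_study(cfg, cohorts = c("train", "test"))
      panel <- train_weight_panel(sim, 0.03, 0.03)
      Etr <- impute_expression(sim$geno_train, panel, tissue = "tissue01")
      Ete <- impute_expression(sim$geno_test, panel, tissue = "tissue01")
      eff <- train_gene_effects(
        sim$train$phenotype, Etr,
        training_covariates(sim$train$covariates[, 1],
                            sim$train$covariates[, 2]))
      attr(evaluate_incremental_r2(
        sim$test$phenotype, build_profiles(Ete[, eff$gene_id], eff),
        sim$test$covariates), "best")
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(sizes, inc, method = "spearman"), 0)
})

test_that("PRS multiplicity bookkeeping is plain arithmetic", {
  m <- prs_multiplicity(1, 1, 1, 1, alpha = 0.05)
  expect_equal(m$n_tests, 2)
  expect_equal(m$threshold, 0.025)
  set.seed(58)
  for (i in 1:10) {
    a <- sample(1:200, 4)
    m <- prs_multiplicity(a[1], a[2], a[3], a[4])
    expect_equal(m$n_tests, a[1] * a[2] + a[3] * a[4])
    expect_equal(m$threshold, 0.05 / m$n_tests)
  }
  expect_error(prs_multiplicity(0, 1, 1, 1), "positive")
})
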