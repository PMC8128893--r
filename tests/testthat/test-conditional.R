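# Conditional analysis on the strongest imputation-model variant.

test_that("top model variant selection and tie-breaks", {
  w <- data.frame(snp_id = c("s1", "s2", "s3"), weight = c(0.2, 0.5, -0.1))
  gw <- data.frame(snp = c("s1", "s2", "s3"), pos = c(10, 20, 30),
                   p = c(1e-4, 1e-9, 0.2))
  expect_equal(pick_top_model_variant(w, gw), "s2")
  # tie in p -> smaller position
  gw$p <- c(1e-4, 1e-4, 1e-4)
  expect_equal(pick_top_model_variant(w, gw), "s1")
  # zero-weight SNPs are ignored
  w2 <- w; w2$weight[1] <- 0
  expect_equal(pick_top_model_variant(w2, gw), "s2")
  # no overlap -> NA with warning
  gw0 <- data.frame(snp = "zz", pos = 1, p = 0.5)
  expect_warning(v <- pick_top_model_variant(w, gw0), "skipped")
  expect_true(is.na(v))
  # 200-SNP fixture equals the argmin oracle
  set.seed(23)
  wb <- data.frame(snp_id = sprintf("s%03d", 1:200), weight = rnorm(200))
  gb <- data.frame(snp = sample(wb$snp_id), pos = sample(1:1e6, 200))
  gb$p <- runif(200)
  want <- gb$snp[which.min(gb$p)]
  expect_equal(pick_top_model_variant(wb, gb), want)
})

test_that("conditional_z handles collinear and independent limits", {
  # single-SNP model conditioned on that SNP: fully explained
  r <- conditional_z(w = 1, z = 3, D = matrix(1), v = 1, n = 5000)
  expect_equal(r$flag, "fully_explained")
  expect_equal(r$p, 1)
  # r_Ev = 0: conditional z equals marginal z up to the df correction
  D <- diag(3)
  w <- c(0.7, -0.4, 0)
  z <- c(2.1, 1.4, 0.8)
  marg <- twas_z(w, z, D, ridge = 0)$z
  cond <- conditional_z(w, z, D, v = 3, n = 5000)
  expect_equal(cond$flag, "ok")
  expect_lt(abs(cond$z - marg) / abs(marg), 0.01)
  expect_error(conditional_z(w, z, D, v = 3, n = 3), "exceed")
})

test_that("summary-statistic conditional test matches two-predictor OLS", {
  cfg <- sim_config(n_genes = 10, n_gwas = 3000, n_ref = 300, cis_h2 = 0.4,
                    mediated_h2 = 0.15, seed = 37)
  sim <- simulate_study(cfg, cohorts = "gwas")
  panel <- oracle_weight_panel(sim)
  ld_in <- ld_from_genotypes(sim$geno_gwas)
  yres <- residualize(sim$gwas$phenotype, sim$gwas$covariates)
  zs <- zo <- numeric(0)
  for (g in unique(panel$gene_id)) {
    wt <- panel[panel$gene_id == g & panel$tissue_id == "tissue01", ]
    al <- harmonize_alleles(wt, sim$gwas$gwas, ld_in[[g]])
    vid <- pick_top_model_variant(
      data.frame(snp_id = al$snps, weight = al$w), sim$gwas$gwas)
    v <- match(vid, al$snps)
    got <- conditional_z(al$w, al$z, al$D, v, cfg$n_gwas)
    if (got$flag != "ok") next
    Xs <- scale(sim$geno_gwas$X[, al$snps, drop = FALSE])
    e_hat <- as.vector(Xs %*% al$w)
    want <- oracle_ols_z(yres, e_hat,
                         covars = data.frame(v = Xs[, v]))
    zs <- c(zs, got$t)
    zo <- c(zo, want)
  }
  expect_gte(length(zs), 8)
  expect_gt(cor(zs, zo), 0.99)
  expect_lt(max(abs(zs - zo)), 0.2)
})

test_that("conditioning on an LD-free variant barely moves the statistic", {
  set.seed(41)
  p <- 6
  D <- diag(p)
  w <- c(rnorm(p - 1), 0)
  z <- rnorm(p, sd = 1.5)
  n <- 5000
  marg <- twas_z(w, z, D, ridge = 0)$z
  cond <- conditional_z(w, z, D, v = p, n = n)
  expect_lt(abs(cond$z - marg) / max(abs(marg), 1e-8), 0.01)
})

test_that("combined conditional p-values classify persistence", {
  S <- diag(3)
  flat <- lapply(1:3, function(i) list(z = 0, p = 1, flag = "ok"))
  cb <- combine_conditional(flat, S, B = 1200, seed = 2)
  expect_equal(cb$class, "p>0.05")
  expect_equal(cb$p_gbj, 1, tolerance = 2 / 1201)
  # all tissues collinear-flagged
  co <- lapply(1:3, function(i) list(z = 0, p = 1, flag = "fully_explained"))
  expect_equal(combine_conditional(co, S)$class, "fully_explained")
  # strong conditional signal lands in a stringent class
  hot <- lapply(c(6, 5.5, 6.2), function(z) list(z = z, p = 0, flag = "ok"))
  cb2 <- combine_conditional(hot, S, B = 2000, seed = 2)
  expect_true(cb2$class %in% c("p<=1e-3", "p<=1e-6"))
  expect_lte(cb2$p_gbj, 1e-3)
})

test_that("multi-variant signals persist after conditioning, single-variant ones do not", {
  # five equal causal eQTLs: conditioning on one variant leaves signal
  cfg_multi <- sim_config(n_genes = 4, snps_per_gene = 10, n_tissues = 4,
                          n_gwas = 20000, n_ref = 500, ld_rho = 0.2,
                          cis_h2 = 0.5, n_causal_eqtl_per_gene = 5,
                          mediated_h2 = 0.25, direct_h2 = 0, seed = 43)
  sim_m <- simulate_study(cfg_multi, cohorts = "gwas")
  res_m <- run_conditional(oracle_weight_panel(sim_m), sim_m$gwas$gwas,
                           sim_m$ld, n = cfg_multi$n_gwas, B = 1500,
                           seed = 5)
  cls_m <- unique(res_m[, c("gene_id", "class")])$class
  expect_gte(sum(cls_m %in% c("p<=1e-3", "p<=1e-6")), 2)
  # single causal eQTL: the top variant explains the association
  cfg_one <- sim_config(n_genes = 4, snps_per_gene = 10, n_tissues = 4,
                        n_gwas = 20000, n_ref = 500, ld_rho = 0.2,
                        cis_h2 = 0.5, n_causal_eqtl_per_gene = 1,
                        mediated_h2 = 0.25, direct_h2 = 0, seed = 44)
  sim_1 <- simulate_study(cfg_one, cohorts = "gwas")
  res_1 <- run_conditional(oracle_weight_panel(sim_1), sim_1$gwas$gwas,
                           sim_1$ld, n = cfg_one$n_gwas, B = 1500, seed = 5)
  cls_1 <- unique(res_1[, c("gene_id", "class")])$class
  expect_gte(sum(cls_1 %in% c("p>0.05", "fully_explained")), 3)
})
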