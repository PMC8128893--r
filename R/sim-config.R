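#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' small but realistic imaging-genetics world: LD-blocked cis regions of ten
#' SNPs per gene, a GTEx-sized multi-tissue reference panel, moderately
#' heritable expression with shared cross-tissue eQTL effects, and a polygenic
#' phenotype whose genetic variance flows partly through gene expression and
#' partly through direct SNP effects.
#'
#' @param n_ref Reference-panel size (individuals with genotypes and
#'   multi-tissue expression; GTEx panels are a few hundred donors).
#' @param n_gwas GWAS cohort size used to produce summary statistics.
#' @param n_train,n_test Training and testing cohort sizes for polygenic
#'   score construction and evaluation.
#' @param n_genes Number of genes (one LD block per gene).
#' @param snps_per_gene Number of cis SNPs per gene block.
#' @param n_tissues Number of expression panels ("tissues").
#' @param ld_rho Adjacent-SNP dosage correlation within a block, in `[0, 1)`.
#'   Realized as a first-order autoregressive chain on latent haplotype
#'   Gaussians, calibrated so the dosage-scale correlation matches this value.
#' @param maf_range Length-2 vector of minor-allele-frequency bounds in
#'   `(0, 0.5]`.
#' @param cis_h2 Per-tissue cis heritability of expression, in `[0, 1)`.
#' @param cross_tissue_cor Correlation of causal eQTL effect sizes across
#'   tissues, in `[0, 1]` (1 = identical effects in every tissue).
#' @param n_causal_eqtl_per_gene Causal cis-eQTLs per gene.
#' @param mediated_h2 Share of (covariate-adjusted) phenotype variance
#'   mediated by genetically regulated expression.
#' @param direct_h2 Share of phenotype variance from direct (non-mediated)
#'   SNP effects. `mediated_h2 + direct_h2` must be `< 1`.
#' @param n_covariates Number of covariates: the first is a standard-normal
#'   age-like column, the second a Bernoulli(0.5) sex-like column, any
#'   further ones standard normal.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return An object of class `xtwas_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 5, n_gwas = 500, seed = 1)
#' cfg$mediated_h2
sim_config <- function(n_ref = 800L, n_gwas = 5000L,
                       n_train = 5000L, n_test = 2000L,
                       n_genes = 50L, snps_per_gene = 10L, n_tissues = 10L,
                       ld_rho = 0.5, maf_range = c(0.05, 0.5),
                       cis_h2 = 0.3, cross_tissue_cor = 0.7,
                       n_causal_eqtl_per_gene = 3L,
                       mediated_h2 = 0.10, direct_h2 = 0.10,
                       n_covariates = 2L, seed = 1L) {
  cfg <- list(n_ref = as.integer(n_ref), n_gwas = as.integer(n_gwas),
              n_train = as.integer(n_train), n_test = as.integer(n_test),
              n_genes = as.integer(n_genes),
              snps_per_gene = as.integer(snps_per_gene),
              n_tissues = as.integer(n_tissues),
              ld_rho = ld_rho, maf_range = as.numeric(maf_range),
              cis_h2 = cis_h2, cross_tissue_cor = cross_tissue_cor,
              n_causal_eqtl_per_gene = as.integer(n_causal_eqtl_per_gene),
              mediated_h2 = mediated_h2, direct_h2 = direct_h2,
              n_covariates = as.integer(n_covariates),
              seed = as.integer(seed))
  assert_that(cfg$ld_rho >= 0 && cfg$ld_rho < 1, "ld_rho must be in [0, 1)")
  assert_that(length(cfg$maf_range) == 2L &&
                all(cfg$maf_range > 0) && all(cfg$maf_range <= 0.5) &&
                cfg$maf_range[1] <= cfg$maf_range[2],
              "maf_range must be an increasing pair in (0, 0.5]")
  assert_that(cfg$cis_h2 >= 0 && cfg$cis_h2 < 1, "cis_h2 must be in [0, 1)")
  assert_that(cfg$cross_tissue_cor >= 0 && cfg$cross_tissue_cor <= 1,
              "cross_tissue_cor must be in [0, 1]")
  assert_that(cfg$mediated_h2 >= 0 && cfg$direct_h2 >= 0 &&
                cfg$mediated_h2 + cfg$direct_h2 < 1,
              "mediated_h2 + direct_h2 must be < 1")
  assert_that(cfg$n_causal_eqtl_per_gene <= cfg$snps_per_gene,
              "n_causal_eqtl_per_gene cannot exceed snps_per_gene")
  assert_that(all(c(cfg$n_ref, cfg$n_genes, cfg$snps_per_gene,
                    cfg$n_tissues) >= 1L), "counts must be positive")
  class(cfg) <- "xtwas_config"
  cfg
}

#' Gene annotation for a simulated study
#'
#' Genes are laid out on rotating chromosomes with 100 kb bodies spaced 3 Mb
#' apart, so that by default no two genes fall within each other's +/- 1 Mb
#' window (tests that need neighbouring genes construct tighter annotations
#' explicitly).
#'
#' @param config An [sim_config()] object.
#' @return A `data.table` with columns `gene_id, chr, start, end`
#'   (1-based, inclusive).
#' @export
make_annotation <- function(config) {
  g <- seq_len(config$n_genes)
  chr <- ((g - 1L) %% 22L) + 1L
  slot <- (g - 1L) %/% 22L
  start <- 1e6 + slot * 3e6
  data.table::data.table(
    gene_id = sprintf("GENE%03d", g),
    chr = chr,
    start = as.integer(start),
    end = as.integer(start + 1e5 - 1)
  )
}
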