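# Genotype simulation: LD-blocked dosages from thresholded AR(1) haplotypes.

# Latent correlation giving a target allele-indicator correlation for
# thresholds t1 = qnorm(maf1), t2 = qnorm(maf2). Thresholding attenuates
# correlation, so the latent value is inflated relative to the target; if the
# target is unreachable the latent correlation saturates just below 1.
#' @noRd
solve_latent_rho <- function(maf1, maf2, target) {
  if (target <= 0) return(0)
  t1 <- qnorm(maf1); t2 <- qnorm(maf2)
  denom <- sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
  f <- function(r) (pbinorm(t1, t2, r) - maf1 * maf2) / denom - target
  hi <- 0.9995
  if (f(hi) <= 0) return(hi)
  uniroot(f, c(0, hi), tol = 1e-9)$root
}

# One haplotype matrix (n x p of 0/1 alleles) from a latent AR(1) chain.
#' @noRd
draw_haplotypes <- function(n, maf, latent_rho) {
  p <- length(maf)
  Z <- matrix(rnorm(n * p), n, p)
  if (p > 1L) {
    for (j in 2:p) {
      r <- latent_rho[j - 1L]
      Z[, j] <- r * Z[, j - 1L] + sqrt(1 - r^2) * Z[, j]
    }
  }
  thr <- matrix(qnorm(maf), n, p, byrow = TRUE)
  (Z < thr) + 0L
}

#' Simulate LD-blocked SNP dosages
#'
#' Each gene contributes an independent LD block of `snps_per_gene` SNPs.
#' Within a block, two haplotypes per individual are drawn from a latent
#' Gaussian AR(1) chain thresholded at each SNP's minor-allele frequency;
#' the dosage is the haplotype sum, so values lie in `{0, 1, 2}` and follow
#' Hardy-Weinberg proportions. Adjacent latent correlations are calibrated
#' (by bivariate-normal root finding) so the realized adjacent-SNP dosage
#' correlation converges to `config$ld_rho` as `n` grows. Blocks of different
#' genes are independent.
#'
#' @param n Number of individuals (positive).
#' @param annotation Gene table from [make_annotation()] (or same columns).
#' @param config An [sim_config()] object.
#' @param snps Optional SNP table from a previous call (to genotype a new
#'   cohort at the same SNPs, with the same MAFs and calibrated LD).
#' @return An `xtwas_genotypes` object: list with integer matrix `X`
#'   (n x SNPs, dosages, column names = SNP ids) and `snps`, a `data.table`
#'   with `snp, gene_id, chr, pos, a1, a2, maf, latent_rho`. `a1` is the
#'   counted (effect) allele of the dosage.
#' @export
simulate_genotypes <- function(n, annotation, config, snps = NULL) {
  assert_that(length(n) == 1L && n >= 1, "n must be a positive count")
  assert_that(NROW(annotation) >= 1L, "annotation must be non-empty")
  if (is.null(snps)) snps <- make_snp_table(annotation, config)
  blocks <- split(seq_len(nrow(snps)), snps$gene_id)
  blocks <- blocks[unique(snps$gene_id)]   # preserve input order
  X <- matrix(0L, as.integer(n), nrow(snps))
  for (idx in blocks) {
    maf <- snps$maf[idx]
    lat <- snps$latent_rho[idx]
    lat <- lat[-length(lat)]
    X[, idx] <- draw_haplotypes(n, maf, lat) + draw_haplotypes(n, maf, lat)
  }
  colnames(X) <- snps$snp
  structure(list(X = X, snps = data.table::copy(snps)),
            class = "xtwas_genotypes")
}

# SNP metadata for an annotation: positions evenly spaced along the gene
# body, random allele pairs, MAFs uniform in maf_range, and per-pair latent
# correlations calibrated to ld_rho.
#' @noRd
make_snp_table <- function(annotation, config) {
  p <- config$snps_per_gene
  bases <- c("A", "C", "G", "T")
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    pos <- as.integer(round(seq(g$start, g$end, length.out = p)))
    maf <- runif(p, config$maf_range[1], config$maf_range[2])
    # mostly non-ambiguous pairs, as on genotyping arrays; ~10% A/T or C/G
    # strand-ambiguous SNPs keep the harmonization drop rule exercised
    al <- t(vapply(seq_len(p), function(j) {
      repeat {
        a <- sample(bases, 2L)
        ambiguous <- paste(a, collapse = "/") %in%
          c("A/T", "T/A", "C/G", "G/C")
        if (!ambiguous || runif(1) < 0.25) return(a)
      }
    }, character(2L)))
    lat <- if (p > 1L) {
      c(vapply(seq_len(p - 1L), function(j) {
        solve_latent_rho(maf[j], maf[j + 1L], config$ld_rho)
      }, numeric(1)), 0)
    } else 0
    out[[i]] <- data.table::data.table(
      snp = sprintf("%s_snp%02d", g$gene_id, seq_len(p)),
      gene_id = g$gene_id, chr = g$chr, pos = pos,
      a1 = al[, 1], a2 = al[, 2], maf = maf, latent_rho = lat)
  }
  data.table::rbindlist(out)
}

#' Per-gene LD reference from genotypes
#'
#' @param genotypes An `xtwas_genotypes` object.
#' @return Named list (by gene) of LD references: each a list with `snps`,
#'   `a1`, `a2` and the SNP correlation matrix `D` (unit diagonal).
#' @export
ld_from_genotypes <- function(genotypes) {
  sp <- genotypes$snps
  lapply(split(seq_len(nrow(sp)), sp$gene_id)[unique(sp$gene_id)],
         function(idx) {
           D <- stats::cor(genotypes$X[, idx, drop = FALSE])
           dimnames(D) <- list(sp$snp[idx], sp$snp[idx])
           list(snps = sp$snp[idx], a1 = sp$a1[idx], a2 = sp$a2[idx], D = D)
         })
}
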