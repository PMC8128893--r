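# Plain-text (TSV) readers and writers for the pipeline's table formats.
# Writing then reading any table reproduces values to full precision
# (numbers serialized at 17 significant digits).

#' @noRd
write_tsv <- function(x, path) {
  x <- data.table::as.data.table(x)
  for (j in names(x)) {
    if (is.double(x[[j]])) {
      data.table::set(x, j = j, value = sprintf("%.17g", x[[j]]))
    }
  }
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
}

#' Write / read a GWAS summary table
#'
#' Columns: `snp, chr, pos, a1, a2, z, n, p`. On read, the p-column (when
#' present) is validated against the two-sided normal p implied by `z`
#' (1e-6 relative tolerance) and SNP ids must be unique.
#'
#' @param gwas GWAS summary `data.table`.
#' @param path File path.
#' @return `read_gwas` returns the validated `data.table`.
#' @export
write_gwas <- function(gwas, path) write_tsv(gwas, path)

#' @rdname write_gwas
#' @export
read_gwas <- function(path) {
  g <- data.table::fread(path, sep = "\t")
  assert_that(!anyDuplicated(g$snp), "duplicate SNP ids in GWAS table")
  if ("p" %in% names(g)) {
    expect <- 2 * pnorm(-abs(g$z))
    rel <- abs(g$p - expect) / pmax(expect, 1e-300)
    assert_that(all(rel < 1e-6 | expect < 1e-12),
                "GWAS p-values inconsistent with z-scores")
  }
  g
}

#' Write / read a weight panel
#'
#' Columns: `gene_id, tissue_id, snp_id, effect_allele, other_allele,
#' weight`. Read applies [validate_weight_panel()].
#'
#' @param panel WeightPanel `data.table`.
#' @param path File path.
#' @export
write_weight_panel <- function(panel, path) write_tsv(panel, path)

#' @rdname write_weight_panel
#' @export
read_weight_panel <- function(path) {
  p <- data.table::fread(path, sep = "\t")
  validate_weight_panel(p)
  p
}

#' Write / read gene annotation (`gene_id, chr, start, end`)
#' @param annotation Annotation table.
#' @param path File path.
#' @export
write_annotation <- function(annotation, path) write_tsv(annotation, path)

#' @rdname write_annotation
#' @export
read_annotation <- function(path) data.table::fread(path, sep = "\t")

#' Write / read a genotype matrix with its SNP sidecar table
#'
#' The dosage matrix goes to `<path>` (one row per subject, tab-separated,
#' header = SNP ids) and the SNP table to `<path>.snps`.
#'
#' @param genotypes An `xtwas_genotypes` object.
#' @param path Base file path.
#' @export
write_genotypes <- function(genotypes, path) {
  write_tsv(data.table::as.data.table(genotypes$X), path)
  write_tsv(genotypes$snps, paste0(path, ".snps"))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  X <- as.matrix(data.table::fread(path, sep = "\t"))
  storage.mode(X) <- "integer"
  structure(list(X = X, snps = data.table::fread(paste0(path, ".snps"),
                                                 sep = "\t")),
            class = "xtwas_genotypes")
}
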