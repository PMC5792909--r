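#' Construct a genotype matrix
#'
#' The in-memory genotype container used throughout the package: an
#' n-samples x n-SNPs matrix of minor-allele dosages in \{0, 1, 2\} with `NA`
#' marking missing calls, together with a per-SNP annotation table.
#'
#' @param dosage numeric or integer matrix, samples in rows, SNPs in columns;
#'   values must be 0, 1, 2 or `NA`.
#' @param snps data.frame with one row per SNP column and columns
#'   `id`, `chrom`, `pos`, `minor`, `major` and optionally `maf`
#'   (`NA` until computed by [filter_maf()]).
#' @param sample_ids character vector of sample identifiers, one per row.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (integer matrix with dimnames), `snps` (annotation data.frame)
#'   and `sample_ids`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                      data.frame(id = c("rs1", "rs2"), chrom = "1",
#'                                 pos = c(100L, 200L), minor = "A", major = "G"),
#'                      c("s1", "s2"))
#' g
#' @export
genotype_matrix <- function(dosage, snps, sample_ids) {
  dosage <- as.matrix(dosage)
  if (!is.data.frame(snps)) stop("`snps` must be a data.frame")
  req <- c("id", "chrom", "pos", "minor", "major")
  miss <- setdiff(req, names(snps))
  if (length(miss)) stop("`snps` is missing column(s): ", paste(miss, collapse = ", "))
  if (!"maf" %in% names(snps)) snps$maf <- NA_real_
  if (nrow(snps) != ncol(dosage))
    stop("snps table has ", nrow(snps), " rows but dosage has ", ncol(dosage), " columns")
  if (length(sample_ids) != nrow(dosage))
    stop("sample_ids has length ", length(sample_ids), " but dosage has ",
         nrow(dosage), " rows")
  if (anyDuplicated(snps$id)) stop("duplicated SNP ids")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop("dosage contains value outside {0,1,2,NA}: ", dosage[idx])
  }
  if (any(snps$pos < 1, na.rm = TRUE)) stop("SNP positions must be >= 1")
  if (any(snps$minor == snps$major)) stop("minor and major allele must differ")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(as.character(sample_ids), as.character(snps$id))
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  rownames(snps) <- NULL
  structure(list(dosage = dosage, snps = snps,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  nmiss <- sum(is.na(x$dosage))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$dosage)))
  cat("  chromosomes: ", paste(unique(x$snps$chrom), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param genotypes a [genotype_matrix()]
#' @param samples character vector of sample ids or logical/integer index;
#'   `NULL` keeps all.
#' @param snps character vector of SNP ids or logical/integer index;
#'   `NULL` keeps all.
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(genotypes, samples = NULL, snps = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ridx <- seq_len(nrow(genotypes$dosage))
  cidx <- seq_len(ncol(genotypes$dosage))
  if (!is.null(samples)) {
    ridx <- if (is.character(samples)) match(samples, genotypes$sample_ids) else ridx[samples]
    if (anyNA(ridx)) stop("unknown sample id(s): ",
                          paste(samples[is.na(match(samples, genotypes$sample_ids))], collapse = ", "))
  }
  if (!is.null(snps)) {
    cidx <- if (is.character(snps)) match(snps, genotypes$snps$id) else cidx[snps]
    if (anyNA(cidx)) stop("unknown SNP id(s): ",
                          paste(snps[is.na(match(snps, genotypes$snps$id))], collapse = ", "))
  }
  genotype_matrix(genotypes$dosage[ridx, cidx, drop = FALSE],
                  genotypes$snps[cidx, , drop = FALSE],
                  genotypes$sample_ids[ridx])
}
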