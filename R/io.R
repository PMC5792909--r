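#' Read a biallelic VCF into a genotype matrix
#'
#' Parses a VCF (v4.x) with GT fields and returns minor-allele dosages that
#' count copies of the ALT allele. In files written by [write_vcf()] the ALT
#' allele is the minor allele, so ALT dosage equals minor-allele dosage.
#' Missing calls (`./.` or `.`) become `NA`. Sample order is preserved.
#'
#' @param path path to an uncompressed or gzipped VCF file
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm)))   # a single record collapses to a named vector
    fixm <- matrix(fixm, nrow = 1L, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    k <- which(multi)[1L]
    stop("multiallelic record not supported at ", fix$CHROM[k], ":", fix$POS[k],
         " (", fix$ID[k], ")")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  # number of meta lines + 1 header line locates each record's file line
  n_meta <- length(v@meta)
  alleles <- gsub("\\|", "/", gt)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  flat <- known[alleles]
  dim(flat) <- dim(alleles)
  missing_gt <- alleles %in% c("./.", ".") ; dim(missing_gt) <- dim(alleles)
  bad <- is.na(flat) & !missing_gt & !is.na(alleles)
  if (any(bad)) {
    k <- which(bad, arr.ind = TRUE)[1L, ]
    stop("malformed GT '", gt[k[1L], k[2L]], "' for sample ",
         colnames(gt)[k[2L]], " at VCF data line ", k[1L],
         " (file line ", n_meta + 1L + k[1L], ")")
  }
  dose <- flat
  snps <- data.frame(id = fix$ID, chrom = as.character(fix$CHROM),
                     pos = as.integer(fix$POS),
                     minor = fix$ALT, major = fix$REF,
                     stringsAsFactors = FALSE)
  noid <- is.na(snps$id) | snps$id == "."
  snps$id[noid] <- paste0(snps$chrom[noid], ":", snps$pos[noid])
  genotype_matrix(t(dose), snps, colnames(gt))
}

#' Write a genotype matrix as a plain-text biallelic VCF
#'
#' Emits an uncompressed VCF v4.2 with GT-only genotype columns. The minor
#' allele is written as ALT so that ALT dosage round-trips to minor-allele
#' dosage; missing calls are written `./.`.
#'
#' @param genotypes a [genotype_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  s <- genotypes$snps
  gt_codes <- c("0/0", "0/1", "1/1")
  d <- genotypes$dosage
  lines <- c("##fileformat=VCFv4.2",
             "##source=lipidgrs",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(s)), function(k) {
    g <- d[, k]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    paste(c(s$chrom[k], s$pos[k], s$id[k], s$major[k], s$minor[k], ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a dosage-matrix TSV
#'
#' Tab-delimited dialect: header row of SNP ids, first column the sample id,
#' cells in \{0, 1, 2, NA\}. SNP annotation (chromosome, position, alleles)
#' is not carried by this dialect; it can be supplied via `snps` or defaults
#' to placeholders.
#'
#' @param path input path
#' @param snps optional SNP annotation data.frame (columns `id`, `chrom`,
#'   `pos`, `minor`, `major`) matched by id.
#' @return a [genotype_matrix()]
#' @export
read_dosage_tsv <- function(path, snps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("dosage TSV needs a sample-id column plus SNP columns")
  sample_ids <- as.character(d[[1L]])
  mat <- as.matrix(d[, -1L, drop = FALSE])
  ok <- is.na(mat) | mat == 0 | mat == 1 | mat == 2
  if (!all(ok)) {
    k <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("invalid dosage value '", mat[k[1L], k[2L]], "' at row ", k[1L],
         ", column '", colnames(mat)[k[2L]], "'")
  }
  ids <- colnames(mat)
  mat <- matrix(as.numeric(mat), nrow = nrow(mat), dimnames = dimnames(mat))
  if (is.null(snps)) {
    snps <- data.frame(id = ids, chrom = "0", pos = seq_along(ids),
                       minor = "A", major = "B", stringsAsFactors = FALSE)
  } else {
    m <- match(ids, snps$id)
    if (anyNA(m)) stop("SNP annotation missing for: ",
                       paste(ids[is.na(m)], collapse = ", "))
    snps <- snps[m, , drop = FALSE]
  }
  genotype_matrix(mat, snps, sample_ids)
}

#' Write a genotype matrix as a dosage TSV
#'
#' @param genotypes a [genotype_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- as.data.frame(genotypes$dosage, check.names = FALSE)
  out <- cbind(data.frame(sample_id = genotypes$sample_ids,
                          stringsAsFactors = FALSE), d)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects tab-delimited columns `sample_id`, `sex` (0 = male, 1 = female),
#' `age` (years), `bmi` (kg/m^2), `tc`, `tg`, `hdl` (mg/dL). The analysis
#' traits `tc_hdl_ratio` = TC/HDL-c and `log_tg_hdl_ratio` = log10(TG)/HDL-c
#' are computed on read; rows with non-positive lipid values are excluded
#' with a message and recorded in the `excluded` attribute.
#'
#' @param path input path
#' @return data.frame of class `phenotype_table`
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "sex", "age", "bmi", "tc", "tg", "hdl")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("phenotype file is missing column(s): ",
                         paste(miss, collapse = ", "))
  d$sample_id <- as.character(d$sample_id)
  if (!all(d$sex %in% c(0, 1, NA))) stop("sex must be coded 0 (male) / 1 (female)")
  build_traits(d)
}

#' Write a phenotype table
#'
#' Writes the raw columns only (`sample_id`, `sex`, `age`, `bmi`, `tc`,
#' `tg`, `hdl`); derived ratio columns are recomputed on read.
#'
#' @param phenotypes a phenotype data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(phenotypes, path) {
  cols <- c("sample_id", "sex", "age", "bmi", "tc", "tg", "hdl")
  miss <- setdiff(cols, names(phenotypes))
  if (length(miss)) stop("phenotype table is missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- phenotypes[, cols]
  for (v in c("age", "bmi", "tc", "tg", "hdl"))
    out[[v]] <- sprintf("%.10g", out[[v]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GWAS anchor list
#'
#' Tab-delimited columns `rsid`, `chrom`, `pos` (1-based bp).
#'
#' @param path input path
#' @return data.frame with character `rsid`/`chrom` and integer `pos`
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = list(chrom = "character"))
  miss <- setdiff(c("rsid", "chrom", "pos"), names(d))
  if (length(miss)) stop("anchor file is missing column(s): ",
                         paste(miss, collapse = ", "))
  d$rsid <- as.character(d$rsid)
  d$chrom <- as.character(d$chrom)
  d$pos <- as.integer(d$pos)
  if (any(is.na(d$pos)) || any(d$pos < 1)) stop("anchor positions must be integers >= 1")
  d
}

#' Write a GWAS anchor list
#' @param anchors data.frame with columns `rsid`, `chrom`, `pos`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_anchors <- function(anchors, path) {
  write.table(anchors[, c("rsid", "chrom", "pos")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
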