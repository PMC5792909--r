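#' Minor allele frequency from genotype counts
#'
#' MAF = (n_het + 2 * n_minor_hom) / (2 * n_total), with missing genotypes
#' excluded from the counts. For the published rs4420638 counts
#' (6181, 1502, 112) this gives 0.111 to three decimals.
#'
#' @param count_major_hom,count_het,count_minor_hom non-negative genotype
#'   counts (major homozygote, heterozygote, minor homozygote).
#' @return minor allele frequency in \[0, 1\] (values above 0.5 indicate the
#'   "minor" labelling is inverted for these counts).
#' @examples
#' compute_maf(6181, 1502, 112) # 0.1107
#' @export
compute_maf <- function(count_major_hom, count_het, count_minor_hom) {
  counts <- c(count_major_hom, count_het, count_minor_hom)
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be three non-negative numbers")
  total <- sum(counts)
  if (total == 0) stop("all genotype counts are zero; MAF undefined")
  (count_het + 2 * count_minor_hom) / (2 * total)
}

new_qc_report <- function(step, samples_removed, snps_removed, thresholds,
                          n_samples_in, n_snps_in) {
  structure(list(step = step,
                 samples_removed = samples_removed,
                 snps_removed = snps_removed,
                 thresholds = thresholds,
                 n_samples_in = n_samples_in,
                 n_snps_in = n_snps_in),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC step '%s' (thresholds: %s)\n", x$step,
              paste(names(x$thresholds), unlist(x$thresholds),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  samples: %d in, %d removed\n",
              x$n_samples_in, nrow(x$samples_removed)))
  cat(sprintf("  SNPs:    %d in, %d removed\n",
              x$n_snps_in, nrow(x$snps_removed)))
  invisible(x)
}

#' Call-rate filter for samples and SNPs
#'
#' Removes samples with a genotype call rate below `min_rate`, then SNPs with
#' a call rate below `min_rate` computed on the remaining samples. The order
#' matters: dropping a low-quality sample first can rescue a SNP whose
#' missingness was concentrated in that sample.
#'
#' @param genotypes a [genotype_matrix()]
#' @param min_rate minimum fraction of non-missing calls, in (0, 1]
#' @return list with elements `genotypes` (filtered matrix) and `report`
#'   (a `qc_report` listing every removal with its call rate).
#' @export
filter_call_rate <- function(genotypes, min_rate = 0.98) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!(min_rate > 0 && min_rate <= 1)) stop("min_rate must be in (0, 1]")
  d <- genotypes$dosage
  sample_cr <- rowMeans(!is.na(d))
  bad_s <- sample_cr < min_rate
  samples_removed <- data.frame(id = genotypes$sample_ids[bad_s],
                                call_rate = unname(sample_cr[bad_s]),
                                reason = rep_len("call_rate_below_threshold",
                                                 sum(bad_s)),
                                stringsAsFactors = FALSE)
  d2 <- d[!bad_s, , drop = FALSE]
  if (nrow(d2) == 0L) stop("all data removed by QC: no samples pass call rate ", min_rate)
  snp_cr <- colMeans(!is.na(d2))
  bad_m <- snp_cr < min_rate
  snps_removed <- data.frame(id = genotypes$snps$id[bad_m],
                             call_rate = unname(snp_cr[bad_m]),
                             reason = rep_len("call_rate_below_threshold",
                                              sum(bad_m)),
                             stringsAsFactors = FALSE)
  if (all(bad_m)) stop("all data removed by QC: no SNPs pass call rate ", min_rate)
  out <- genotype_matrix(d2[, !bad_m, drop = FALSE],
                         genotypes$snps[!bad_m, , drop = FALSE],
                         genotypes$sample_ids[!bad_s])
  report <- new_qc_report("call_rate", samples_removed, snps_removed,
                          list(min_rate = min_rate),
                          nrow(d), ncol(d))
  list(genotypes = out, report = report)
}

#' Minor-allele-frequency filter
#'
#' Computes each SNP's MAF from the observed dosages (missing calls excluded)
#' and removes SNPs with MAF strictly below `min_maf`; a SNP at exactly the
#' threshold is retained. The computed MAF is stored on the retained SNP
#' records.
#'
#' @param genotypes a [genotype_matrix()], normally after [filter_call_rate()]
#' @param min_maf minimum minor allele frequency, default 0.05
#' @return list with elements `genotypes` and `report` (a `qc_report`).
#' @export
filter_maf <- function(genotypes, min_maf = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!(min_maf >= 0 && min_maf <= 0.5)) stop("min_maf must be in [0, 0.5]")
  d <- genotypes$dosage
  freq <- colMeans(d, na.rm = TRUE) / 2     # frequency of the coded (minor) allele
  maf <- pmin(freq, 1 - freq)
  bad <- maf < min_maf | is.nan(maf)
  snps_removed <- data.frame(id = genotypes$snps$id[bad],
                             maf = unname(maf[bad]),
                             reason = rep_len("maf_below_threshold", sum(bad)),
                             stringsAsFactors = FALSE)
  if (all(bad)) stop("all data removed by QC: no SNPs pass MAF ", min_maf)
  snps <- genotypes$snps
  snps$maf <- unname(maf)
  out <- genotype_matrix(d[, !bad, drop = FALSE], snps[!bad, , drop = FALSE],
                         genotypes$sample_ids)
  report <- new_qc_report("maf", data.frame(id = character(), call_rate = numeric(),
                                            reason = character()),
                          snps_removed, list(min_maf = min_maf),
                          nrow(d), ncol(d))
  list(genotypes = out, report = report)
}
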