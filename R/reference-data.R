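#' Published six-SNP reference table for the KARE cholesterol-ratio analysis
#'
#' The six markers the KARE cholesterol-ratio analysis finally selected, with
#' their genomic location, minor/major alleles, minor allele frequency,
#' genotype counts in the 7795-sample cohort, per-genotype mean cholesterol
#' ratios, and the selection-set regression-slope weights for each trait.
#' `trend_sign` is +1 when the minor allele increases the ratios (so the
#' minor allele is the risk allele) and -1 when the major allele does;
#' the `weight_*` columns are the published risk-allele-oriented magnitudes.
#'
#' These values anchor the synthetic cohort generator
#' ([kare_like_scenario()]) and serve as worked-example fixtures.
#'
#' @return data.frame with one row per marker.
#' @examples
#' kare_reference_snps()[, c("marker", "maf", "weight_tc_hdl")]
#' @export
kare_reference_snps <- function() {
  path <- system.file("extdata", "kare_six_snps.tsv", package = "lipidgrs",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, colClasses = list(chrom = "character"))
}

#' Published cross-validation p-value matrix (12 candidate markers)
#'
#' The p-values of the 12 markers that met the dual-trait p <= 0.01 rule on
#' the 7016-sample SNP selection set, across the selection set and the ten
#' 10-fold cross-validation training sets (n = 6314 each), for both analysis
#' traits. Used as the worked example for [apply_threshold_matrix()]: the
#' consistency rule applied to this matrix leaves exactly six markers.
#'
#' @param as_array if `TRUE`, return a 3-d array (marker x set x trait) ready
#'   for [apply_threshold_matrix()]; otherwise the long data.frame.
#' @return data.frame or 3-d numeric array.
#' @examples
#' p <- kare_cv_pvalues(as_array = TRUE)
#' apply_threshold_matrix(p[, "selection_set", , drop = FALSE], alpha = 0.01)
#' @export
kare_cv_pvalues <- function(as_array = FALSE) {
  path <- system.file("extdata", "kare_cv_pvalues.tsv", package = "lipidgrs",
                      mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!as_array) return(d)
  markers <- unique(d$marker)
  sets <- setdiff(names(d), c("marker", "trait"))
  traits <- unique(d$trait)
  arr <- array(NA_real_, dim = c(length(markers), length(sets), length(traits)),
               dimnames = list(markers, sets, traits))
  for (tr in traits) {
    sub <- d[d$trait == tr, ]
    arr[sub$marker, , tr] <- as.matrix(sub[, sets])
  }
  arr
}
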