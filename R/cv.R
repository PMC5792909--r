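#' Build a k-fold cross-validation plan
#'
#' Partitions the samples into k folds by a seeded uniform shuffle; fold
#' sizes are floor(n/k) or ceiling(n/k) and differ by at most one. For the
#' 7016-sample selection set and k = 10 this yields test folds of 701 or 702
#' samples, i.e. training sets of 6314 or 6315.
#'
#' @param sample_ids character vector of sample ids
#' @param k number of folds (>= 2), default 10
#' @param seed integer seed; the plan is deterministic given the seed
#' @return object of class `fold_plan`: list with `k`, `assignment` (named
#'   integer vector mapping sample id to fold in 1..k) and `seed`.
#' @export
make_folds <- function(sample_ids, k = 10L, seed = 1L) {
  n <- length(sample_ids)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("cannot make ", k, " folds from ", n, " samples")
  perm <- with_seed(derive_seed(seed, 101L), sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n)
  fold[perm] <- rep.int(seq_len(k), times = sizes)
  structure(list(k = as.integer(k),
                 assignment = setNames(fold, sample_ids),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sz <- table(x$assignment)
  cat(sprintf("fold_plan: %d samples in %d folds (sizes %s), seed %d\n",
              length(x$assignment), x$k,
              paste(range(sz), collapse = "-"), x$seed))
  invisible(x)
}

#' Dual-trait consistency threshold on a p-value matrix
#'
#' Returns the SNPs whose p-value is at most `alpha` for every trait in
#' every set of the matrix. The comparison is inclusive (p <= alpha): a
#' marker whose largest p-value equals the threshold still passes, matching
#' the published worked example in which the least significant selected
#' marker reached exactly p = 0.01 in two training sets.
#'
#' @param p_matrix 3-d numeric array, SNP x set x trait, with dimnames
#' @param alpha significance threshold, default 0.01
#' @return character vector of passing SNP ids (possibly empty)
#' @examples
#' apply_threshold_matrix(kare_cv_pvalues(as_array = TRUE)) # the six markers
#' @export
apply_threshold_matrix <- function(p_matrix, alpha = 0.01) {
  stopifnot(is.array(p_matrix), length(dim(p_matrix)) == 3L)
  if (anyNA(p_matrix)) {
    k <- which(is.na(p_matrix), arr.ind = TRUE)[1L, ]
    stop("missing p-value for SNP '", dimnames(p_matrix)[[1L]][k[1L]],
         "' in set '", dimnames(p_matrix)[[2L]][k[2L]], "'")
  }
  pass <- apply(p_matrix <= alpha, 1L, all)
  dimnames(p_matrix)[[1L]][pass]
}

#' Cross-validation consistency SNP selection
#'
#' For each of k folds, fits the additive association model on the training
#' portion (all samples except the fold) for every candidate SNP and both
#' traits; within each LD block only the most significant SNP per fold
#' remains eligible (ranked by the TC/HDL-c p-value, tie-broken by the
#' TG/HDL-c p-value, then genomic position). The selected set contains the
#' SNPs that are their block's representative in every fold and satisfy
#' p <= alpha for both traits in every fold.
#'
#' @param genotypes a [genotype_matrix()] (QC already applied)
#' @param phenotypes a phenotype table with traits built
#' @param candidates character vector of candidate SNP ids (default: all
#'   SNPs in `genotypes`)
#' @param k folds, default 10
#' @param alpha per-fold dual-trait threshold, default 0.01 (inclusive)
#' @param seed integer seed governing the fold shuffle
#' @param blocks optional named LD-block labels from [ld_blocks()]; computed
#'   from the r^2 > 0.2 graph on the candidates when `NULL`
#' @param traits the two trait column names
#' @return object of class `cv_selection`: list with `selected`,
#'   `p_matrix` (SNP x fold x trait array), `slope_matrix`, `representative`
#'   (SNP x fold logical), `blocks`, `fold_plan`, `alpha`.
#' @export
run_cv_selection <- function(genotypes, phenotypes, candidates = NULL,
                             k = 10L, alpha = 0.01, seed = 1L, blocks = NULL,
                             traits = c("tc_hdl_ratio", "log_tg_hdl_ratio")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(candidates)) candidates <- genotypes$snps$id
  candidates <- sort(unique(as.character(candidates)))
  if (!all(candidates %in% genotypes$snps$id))
    stop("candidate SNP(s) absent from genotypes: ",
         paste(setdiff(candidates, genotypes$snps$id), collapse = ", "))
  common <- intersect(genotypes$sample_ids, phenotypes$sample_id)
  g <- subset_genotypes(genotypes, samples = common, snps = candidates)
  ph <- phenotypes[match(common, phenotypes$sample_id), , drop = FALSE]
  if (is.null(blocks)) blocks <- ld_blocks(g, candidates)
  blocks <- blocks[candidates]
  plan <- make_folds(common, k = k, seed = seed)
  p_arr <- array(NA_real_, dim = c(length(candidates), k, 2L),
                 dimnames = list(candidates, paste0("fold", seq_len(k)), traits))
  b_arr <- p_arr
  rep_mat <- matrix(FALSE, length(candidates), k,
                    dimnames = list(candidates, paste0("fold", seq_len(k))))
  pos <- g$snps$pos[match(candidates, g$snps$id)]
  for (f in seq_len(k)) {
    train <- common[plan$assignment[common] != f]
    res <- associate_panel(subset_genotypes(g, samples = train), ph[match(train, ph$sample_id), ],
                           traits = traits)
    for (tr in traits) {
      sub <- res[res$trait == tr, ]
      m <- match(sub$snp, candidates)
      p_arr[m, f, tr] <- sub$p
      b_arr[m, f, tr] <- sub$slope
    }
    # one representative per LD block: smallest TC p, then TG p, then position
    p1 <- p_arr[, f, 1L]; p2 <- p_arr[, f, 2L]
    for (b in unique(blocks)) {
      members <- which(blocks == b)
      fitted <- members[!is.na(p1[members])]
      if (!length(fitted)) next
      o <- order(p1[fitted], p2[fitted], pos[fitted])
      rep_mat[fitted[o[1L]], f] <- TRUE
    }
  }
  always_rep <- rownames(rep_mat)[rowSums(rep_mat) == k]
  sub_arr <- p_arr[always_rep, , , drop = FALSE]
  complete <- apply(!is.na(sub_arr), 1L, all)   # a fold failure is a fail
  pass_p <- if (any(complete))
    apply_threshold_matrix(sub_arr[complete, , , drop = FALSE], alpha = alpha)
  else character(0)
  selected <- intersect(always_rep, pass_p)
  if (!length(selected))
    warning("no SNP passed the consistency selection at alpha = ", alpha)
  structure(list(selected = selected, p_matrix = p_arr, slope_matrix = b_arr,
                 representative = rep_mat, blocks = blocks, fold_plan = plan,
                 alpha = alpha, traits = traits),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("cv_selection: %d candidate SNPs, %d folds, alpha = %g\n",
              nrow(x$p_matrix), x$fold_plan$k, x$alpha))
  if (length(x$selected)) {
    cat("  selected (", length(x$selected), "): ",
        paste(x$selected, collapse = ", "), "\n", sep = "")
  } else cat("  selected: none\n")
  invisible(x)
}
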