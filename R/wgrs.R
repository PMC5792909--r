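#' Build risk-allele-oriented wGRS weights from association results
#'
#' For each selected SNP and trait the risk allele is the allele whose count
#' increases the trait: the minor allele when the dosage slope is positive,
#' the major allele otherwise (zero slopes orient to the minor allele by
#' convention). The weight is the absolute regression slope, so all weights
#' are non-negative after orientation — the form the wGRS formula
#' sum_i (risk-allele count_i x weight_i) expects.
#'
#' @param assoc association results from [associate_panel()]
#' @param selected character vector of selected SNP ids
#' @param snps optional SNP annotation (columns `id`, `minor`, `major`) used
#'   to attach risk-allele letters
#' @return object of class `grs_weights`: data.frame with `snp`, `trait`,
#'   `orientation` ("minor"/"major"), `risk_allele`, `weight`, `slope`.
#' @export
build_weights <- function(assoc, selected, snps = NULL) {
  stopifnot(is.data.frame(assoc))
  sub <- assoc[assoc$snp %in% selected, ]
  missing_snp <- setdiff(selected, sub$snp)
  if (length(missing_snp))
    stop("selected SNP(s) absent from association results: ",
         paste(missing_snp, collapse = ", "))
  if (anyNA(sub$slope))
    stop("selected SNP(s) with failed fits: ",
         paste(unique(sub$snp[is.na(sub$slope)]), collapse = ", "))
  w <- data.frame(snp = sub$snp, trait = sub$trait,
                  orientation = ifelse(sub$slope >= 0, "minor", "major"),
                  risk_allele = NA_character_,
                  weight = abs(sub$slope), slope = sub$slope,
                  stringsAsFactors = FALSE)
  if (!is.null(snps)) {
    m <- match(w$snp, snps$id)
    w$risk_allele <- ifelse(w$orientation == "minor",
                            snps$minor[m], snps$major[m])
  }
  w <- w[order(match(w$snp, selected), w$trait), ]
  rownames(w) <- NULL
  structure(w, class = c("grs_weights", "data.frame"))
}

#' Compute per-sample weighted genetic risk scores
#'
#' score_s = sum_i (risk-allele count of sample s at SNP i) x weight_i,
#' where the risk-allele count is the minor-allele dosage for minor-oriented
#' weights and 2 - dosage for major-oriented weights. Missing genotypes
#' contribute the SNP's mean observed risk-allele count (mean imputation,
#' reported via message).
#'
#' @param genotypes a [genotype_matrix()]
#' @param weights a `grs_weights` object from [build_weights()]
#' @param trait which trait's weight set to use (must be present in
#'   `weights$trait`)
#' @return named numeric vector of scores, one per sample
#' @export
compute_wgrs <- function(genotypes, weights, trait) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  w <- weights[weights$trait == trait, , drop = FALSE]
  if (!nrow(w)) stop("no weights for trait '", trait, "'")
  absent <- setdiff(w$snp, genotypes$snps$id)
  if (length(absent)) stop("weight SNP(s) missing from panel: ",
                           paste(absent, collapse = ", "))
  d <- genotypes$dosage[, w$snp, drop = FALSE]
  risk <- d
  flip <- w$orientation == "major"
  risk[, flip] <- 2L - risk[, flip, drop = FALSE]
  if (anyNA(risk)) {
    n_imp <- sum(is.na(risk))
    mu <- colMeans(risk, na.rm = TRUE)
    for (j in seq_len(ncol(risk))) {
      nas <- is.na(risk[, j])
      if (any(nas)) risk[nas, j] <- mu[j]
    }
    message("mean-imputed ", n_imp, " missing genotype call(s) in wGRS")
  }
  drop(risk %*% w$weight) |> setNames(genotypes$sample_ids)
}

#' Rank-based equal-count quartile labels
#'
#' Assigns labels 1 (lowest) to 4 (highest) so that group sizes differ by at
#' most one; ties are broken by stable input order.
#'
#' @param values numeric vector, length >= 4
#' @return integer vector of labels in \{1, 2, 3, 4\}
#' @examples
#' quartile_bin(c(5, 1, 9, 3)) # 3 1 4 2
#' @export
quartile_bin <- function(values) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 values to form quartiles")
  r <- rank(values, ties.method = "first")
  as.integer(ceiling(4 * r / n))
}

#' Quartile trend of wGRS against a phenotype's quartiles
#'
#' Computes the mean wGRS in each phenotype quartile, the least-squares
#' regression of the individual scores on the quartile index (slope and its
#' two-sided p-value, plus `r_squared_individual`), and `r_squared`, the
#' coefficient of determination of the linear fit to the four quartile means
#' — the group-level trend statistic comparable to published quartile-trend
#' R^2 values. An individual-level fit supplies the p-value (a four-point
#' fit cannot produce meaningful significance), while the quartile-mean fit
#' supplies the headline R^2; the two readings are reported side by side.
#'
#' @param scores numeric vector of wGRS values
#' @param quartile_labels integer labels from [quartile_bin()]
#' @param group optional label stored on the result (e.g. "all", "male")
#' @return object of class `trend_result`: list with `quartile_means`,
#'   `slope`, `p_value`, `r_squared`, `r_squared_individual`, `n`, `group`.
#' @export
trend_fit <- function(scores, quartile_labels, group = "all") {
  stopifnot(length(scores) == length(quartile_labels))
  quartile_labels <- as.integer(quartile_labels)
  if (!all(quartile_labels %in% 1:4)) stop("labels must be in 1..4")
  counts <- tabulate(quartile_labels, 4L)
  if (any(counts == 0L)) stop("empty quartile: ",
                              paste(which(counts == 0L), collapse = ", "))
  qm <- as.numeric(tapply(scores, quartile_labels, mean))
  fit <- lm(scores ~ quartile_labels)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legal input here
  slope <- unname(coef(fit)[2L])
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  r2_ind <- sm$r.squared
  # goodness of the linear trend at the quartile-mean level
  if (var(qm) > 0) {
    mfit <- lm(qm ~ I(1:4))
    r2_means <- suppressWarnings(summary(mfit))$r.squared
  } else r2_means <- 0
  structure(list(quartile_means = qm, slope = slope, p_value = p,
                 r_squared = r2_means, r_squared_individual = r2_ind,
                 n = length(scores), group = group),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend_result [%s], n = %d\n", x$group, x$n))
  cat("  quartile means:", paste(sprintf("%.4g", x$quartile_means),
                                 collapse = ", "), "\n")
  cat(sprintf("  slope = %.4g, p = %.3g, R2 (quartile means) = %.4f, R2 (individual) = %.4f\n",
              x$slope, x$p_value, x$r_squared, x$r_squared_individual))
  invisible(x)
}

#' Evaluate training-set weights on a holdout cohort
#'
#' Fits per-SNP association models on the training cohort only, builds
#' risk-allele weights for the selected SNPs, applies them unchanged to the
#' holdout samples, and evaluates the quartile trend per group (all, male,
#' female). By default holdout samples are binned by the holdout's own
#' ratio quartiles; `cutpoints = "training"` instead carries the training
#' quartile cut-points over.
#'
#' @param train_genotypes,train_phenotypes training cohort
#' @param holdout_genotypes,holdout_phenotypes holdout cohort
#' @param selected character vector of selected SNP ids
#' @param traits trait column names
#' @param cutpoints `"holdout"` (default) or `"training"`
#' @return nested list: `result[[trait]][[group]]` is a [trend_fit()] result;
#'   the fitted weights are attached as attribute `weights`.
#' @export
evaluate_holdout <- function(train_genotypes, train_phenotypes,
                             holdout_genotypes, holdout_phenotypes,
                             selected,
                             traits = c("tc_hdl_ratio", "log_tg_hdl_ratio"),
                             cutpoints = c("holdout", "training")) {
  cutpoints <- match.arg(cutpoints)
  assoc <- associate_panel(subset_genotypes(train_genotypes, snps = selected),
                           train_phenotypes, traits = traits)
  w <- build_weights(assoc, selected, snps = train_genotypes$snps)
  out <- list()
  hp <- holdout_phenotypes
  groups <- list(all = rep(TRUE, nrow(hp)), male = hp$sex == 0, female = hp$sex == 1)
  for (tr in traits) {
    scores <- compute_wgrs(holdout_genotypes, w, tr)
    scores <- scores[hp$sample_id]
    out[[tr]] <- list()
    for (gname in names(groups)) {
      sel <- groups[[gname]] & !is.na(hp[[tr]])
      if (sum(sel) < 4L) next
      vals <- hp[[tr]][sel]
      labs <- if (cutpoints == "holdout") {
        quartile_bin(vals)
      } else {
        br <- quantile(train_phenotypes[[tr]], probs = c(0.25, 0.5, 0.75),
                       na.rm = TRUE, type = 7)
        as.integer(findInterval(vals, br, left.open = TRUE) + 1L)
      }
      out[[tr]][[gname]] <- trend_fit(scores[sel], labs, group = gname)
    }
  }
  attr(out, "weights") <- w
  out
}
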