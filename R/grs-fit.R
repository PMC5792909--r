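#' Fit a cross-validated weighted genetic risk score model
#'
#' The package's central fitting function. Runs the k-fold consistency
#' selection ([run_cv_selection()]) over the candidate SNPs, refits the
#' per-SNP association models on the full selection set to obtain the
#' risk-allele weights ([build_weights()]), computes per-sample wGRS for
#' both traits, and evaluates the quartile trend of the scores against each
#' trait's quartiles ([trend_fit()]).
#'
#' @param genotypes a [genotype_matrix()] (after QC)
#' @param phenotypes a phenotype table; traits are built with
#'   [build_traits()] if absent
#' @param candidates candidate SNP ids (default: all SNPs in the panel)
#' @param k number of cross-validation folds, default 10
#' @param alpha per-fold dual-trait p threshold (inclusive), default 0.01
#' @param seed integer seed for the fold shuffle
#' @param traits the two trait column names
#' @return object of class `grs_fit` with components `selection`
#'   (a `cv_selection`), `weights` (a `grs_weights`), `scores` (named list
#'   per trait), `trends` (list per trait of `trend_result`), `traits`,
#'   `snps` (annotation of the selected SNPs), and `call`.
#' @seealso [predict.grs_fit()], [coef.grs_fit()], [plot.grs_fit()]
#' @examples
#' \donttest{
#' sc <- kare_like_scenario(seed = 7, n = 1500)
#' fit <- grs_fit(sc$genotypes, sc$phenotypes, candidates = sc$causal,
#'                seed = 7)
#' fit
#' }
#' @export
grs_fit <- function(genotypes, phenotypes, candidates = NULL, k = 10L,
                    alpha = 0.01, seed = 1L,
                    traits = c("tc_hdl_ratio", "log_tg_hdl_ratio")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!all(traits %in% names(phenotypes))) phenotypes <- build_traits(phenotypes)
  selection <- run_cv_selection(genotypes, phenotypes, candidates = candidates,
                                k = k, alpha = alpha, seed = seed,
                                traits = traits)
  weights <- NULL; scores <- list(); trends <- list()
  if (length(selection$selected)) {
    assoc <- associate_panel(
      subset_genotypes(genotypes, snps = selection$selected),
      phenotypes, traits = traits)
    weights <- build_weights(assoc, selection$selected, snps = genotypes$snps)
    common <- intersect(genotypes$sample_ids, phenotypes$sample_id)
    g <- subset_genotypes(genotypes, samples = common)
    ph <- phenotypes[match(common, phenotypes$sample_id), ]
    for (tr in traits) {
      sc <- compute_wgrs(g, weights, tr)
      ok <- !is.na(ph[[tr]])
      labs <- quartile_bin(ph[[tr]][ok])
      scores[[tr]] <- sc
      trends[[tr]] <- trend_fit(sc[ok], labs)
    }
  }
  structure(list(selection = selection, weights = weights, scores = scores,
                 trends = trends, traits = traits,
                 snps = genotypes$snps[genotypes$snps$id %in% selection$selected, ,
                                       drop = FALSE],
                 call = match.call()),
            class = "grs_fit")
}

#' @export
print.grs_fit <- function(x, ...) {
  cat("Cross-validated weighted genetic risk score fit\n")
  cat(sprintf("  %d-fold selection at alpha = %g: %d SNP(s) selected\n",
              x$selection$fold_plan$k, x$selection$alpha,
              length(x$selection$selected)))
  if (!is.null(x$weights)) {
    cat("  weights (risk-allele oriented):\n")
    w <- as.data.frame(x$weights)
    for (tr in x$traits) {
      sub <- w[w$trait == tr, ]
      cat(sprintf("    %s: %s\n", tr,
                  paste(sprintf("%s=%.4g", sub$snp, sub$weight), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
summary.grs_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.grs_fit")
}

#' @export
print.summary.grs_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (length(fit$trends)) {
    cat("  quartile trends (score vs trait quartile):\n")
    for (tr in names(fit$trends)) {
      t <- fit$trends[[tr]]
      cat(sprintf("    %s: means %s; slope %.4g, p %.3g, R2 %.4f\n", tr,
                  paste(sprintf("%.3g", t$quartile_means), collapse = "/"),
                  t$slope, t$p_value, t$r_squared))
    }
  }
  p <- fit$selection$p_matrix
  if (length(fit$selection$selected)) {
    cat("  per-fold p-value range of selected SNPs:\n")
    for (s in fit$selection$selected)
      cat(sprintf("    %s: %.3g - %.3g\n", s,
                  min(p[s, , ]), max(p[s, , ])))
  }
  invisible(x)
}

#' Extract wGRS weights from a fitted model
#'
#' @param object a [grs_fit()] object
#' @param ... unused
#' @return numeric matrix, selected SNPs x traits, of risk-allele-oriented
#'   weights (`NULL` if nothing was selected)
#' @export
coef.grs_fit <- function(object, ...) {
  if (is.null(object$weights)) return(NULL)
  w <- as.data.frame(object$weights)
  snps <- unique(w$snp)
  out <- sapply(object$traits, function(tr)
    w$weight[w$trait == tr][match(snps, w$snp[w$trait == tr])])
  out <- matrix(out, nrow = length(snps),
                dimnames = list(snps, object$traits))
  out
}

#' Predict wGRS for new genotypes
#'
#' Applies the fitted risk-allele weights unchanged to a new genotype panel.
#'
#' @param object a [grs_fit()] object
#' @param newdata a [genotype_matrix()] containing the selected SNPs;
#'   `NULL` returns the training scores
#' @param trait trait whose weight set to apply (default: first trait)
#' @param ... unused
#' @return named numeric vector of scores
#' @export
predict.grs_fit <- function(object, newdata = NULL, trait = NULL, ...) {
  if (is.null(object$weights)) stop("model selected no SNPs; nothing to predict")
  if (is.null(trait)) trait <- object$traits[1L]
  if (is.null(newdata)) return(object$scores[[trait]])
  compute_wgrs(newdata, object$weights, trait)
}

#' Plot quartile trends of a fitted wGRS model
#'
#' Draws the mean wGRS per phenotype quartile for each trait (base
#' graphics), the package's analogue of published wGRS quartile-trend
#' figures.
#'
#' @param x a [grs_fit()] object
#' @param ... passed to [graphics::plot()]
#' @export
plot.grs_fit <- function(x, ...) {
  if (!length(x$trends)) stop("model selected no SNPs; nothing to plot")
  old <- graphics::par(mfrow = c(1, length(x$trends)))
  on.exit(graphics::par(old))
  for (tr in names(x$trends)) {
    t <- x$trends[[tr]]
    graphics::plot(1:4, t$quartile_means, type = "b", pch = 19,
                   xlab = paste(tr, "quartile"), ylab = "mean wGRS",
                   main = sprintf("%s (R2 = %.3f)", tr, t$r_squared), ...)
  }
  invisible(x)
}
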