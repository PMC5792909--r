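#' Build the analysis traits from raw lipid values
#'
#' Adds the two cholesterol-ratio traits to a phenotype table:
#' `tc_hdl_ratio` = TC / HDL-c and `log_tg_hdl_ratio` = log10(TG) / HDL-c.
#' The TG transform is log base 10 applied to the numerator before dividing:
#' with TG = 162 and HDL-c = 49 the trait is log10(162)/49 = 0.0451, the
#' magnitude of published per-genotype TG/HDL-c means, whereas the raw ratio
#' would be ~3.3. Rows with non-positive TC, TG or HDL-c are excluded with a
#' message and listed in the `excluded` attribute.
#'
#' @param phenotypes data.frame with columns `tc`, `tg`, `hdl` (mg/dL)
#' @return the phenotype data.frame with derived trait columns, class
#'   `phenotype_table`
#' @examples
#' build_traits(data.frame(sample_id = "s1", sex = 0, age = 50, bmi = 24,
#'                         tc = 200, tg = 100, hdl = 50))
#' @export
build_traits <- function(phenotypes) {
  stopifnot(is.data.frame(phenotypes))
  miss <- setdiff(c("tc", "tg", "hdl"), names(phenotypes))
  if (length(miss)) stop("phenotype table is missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- with(phenotypes, !(tc > 0 & tg > 0 & hdl > 0))
  bad[is.na(bad)] <- TRUE
  excluded <- phenotypes[bad, , drop = FALSE]
  if (any(bad)) {
    message(sum(bad), " sample(s) excluded: non-positive or missing lipid value")
    phenotypes <- phenotypes[!bad, , drop = FALSE]
  }
  phenotypes$tc_hdl_ratio <- phenotypes$tc / phenotypes$hdl
  phenotypes$log_tg_hdl_ratio <- log10(phenotypes$tg) / phenotypes$hdl
  attr(phenotypes, "excluded") <- excluded
  class(phenotypes) <- unique(c("phenotype_table", class(phenotypes)))
  phenotypes
}

#' Additive single-SNP association fit
#'
#' Ordinary least squares of a trait on minor-allele dosage with age, sex and
#' BMI as covariates: trait ~ intercept + dosage + age + sex + BMI.
#' The reported slope is the dosage coefficient (trait units per minor-allele
#' copy); its p-value is the two-sided t test with n - 5 degrees of freedom.
#' Samples with any missing value are dropped listwise.
#'
#' @param genotype_dosage numeric vector of dosages in \{0,1,2,NA\}
#' @param trait numeric trait vector
#' @param covariates data.frame or matrix with columns `age`, `sex`, `bmi`
#' @return one-row data.frame: `slope`, `se`, `t`, `p`, `n`
#' @export
fit_additive <- function(genotype_dosage, trait, covariates) {
  covariates <- as.data.frame(covariates)
  miss <- setdiff(c("age", "sex", "bmi"), names(covariates))
  if (length(miss)) stop("covariates missing column(s): ", paste(miss, collapse = ", "))
  n0 <- length(trait)
  stopifnot(length(genotype_dosage) == n0, nrow(covariates) == n0)
  keep <- complete.cases(genotype_dosage, trait, covariates[, c("age", "sex", "bmi")])
  g <- genotype_dosage[keep]; y <- trait[keep]
  cv <- covariates[keep, , drop = FALSE]
  n <- length(y)
  if (n < 10L) stop("fewer than 10 complete cases (", n, ")")
  if (length(unique(g)) < 2L) stop("monomorphic in analysis set")
  X <- cbind(`(Intercept)` = 1, dosage = g, age = cv$age, sex = cv$sex, bmi = cv$bmi)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- lm.fit(X, y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  slope <- unname(fit$coefficients["dosage"])
  tval <- slope / se
  p <- 2 * pt(-abs(tval), df)
  data.frame(slope = slope, se = se, t = tval, p = p, n = n)
}

# Vectorized per-SNP OLS over a complete-case dosage matrix via the
# Frisch-Waugh-Lovell identity: residualize trait and dosages on the
# covariate design once, then each SNP slope/se/t/p follows from simple
# regression of the residuals with n - 5 df. Exact match to fit_additive.
fwl_scan <- function(G, y, C) {
  qc <- qr(C)
  yr <- qr.resid(qc, y)
  Gr <- qr.resid(qc, G)
  sxx <- colSums(Gr^2)
  sxy <- colSums(Gr * yr)
  slope <- sxy / sxx
  df <- length(y) - ncol(C) - 1L
  rss <- sum(yr^2) - slope^2 * sxx
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / sxx)
  tval <- slope / se
  p <- 2 * pt(-abs(tval), df)
  data.frame(snp = colnames(G), slope = slope, se = se, t = tval, p = p,
             n = length(y), row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-SNP association scan over a genotype panel
#'
#' Fits the additive model of [fit_additive()] for every SNP and every
#' requested trait. SNPs whose fit fails (for example monomorphic in the
#' analysis set) are flagged in the `note` column rather than aborting the
#' scan. Samples are aligned between genotypes and phenotypes by id;
#' listwise deletion is applied per SNP.
#'
#' @param genotypes a [genotype_matrix()]
#' @param phenotypes a phenotype table containing the trait and covariate
#'   columns (see [build_traits()])
#' @param traits character vector of trait column names,
#'   default `c("tc_hdl_ratio", "log_tg_hdl_ratio")`
#' @return data.frame with one row per SNP x trait: `snp`, `trait`, `slope`,
#'   `se`, `t`, `p`, `n`, `note` (`NA` for clean fits).
#' @export
associate_panel <- function(genotypes, phenotypes,
                            traits = c("tc_hdl_ratio", "log_tg_hdl_ratio")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  miss <- setdiff(c(traits, "age", "sex", "bmi", "sample_id"), names(phenotypes))
  if (length(miss)) stop("phenotype table is missing column(s): ",
                         paste(miss, collapse = ", "))
  common <- intersect(genotypes$sample_ids, phenotypes$sample_id)
  if (!length(common)) stop("no samples shared between genotypes and phenotypes")
  G <- genotypes$dosage[match(common, genotypes$sample_ids), , drop = FALSE]
  ph <- phenotypes[match(common, phenotypes$sample_id), , drop = FALSE]
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    base_ok <- complete.cases(ph[, c(tr, "age", "sex", "bmi")])
    Gb <- G[base_ok, , drop = FALSE]
    yb <- ph[[tr]][base_ok]
    cvb <- ph[base_ok, c("age", "sex", "bmi")]
    poly <- apply(Gb, 2L, function(g) {
      u <- unique(g[!is.na(g)]); length(u) >= 2L
    })
    res <- data.frame(snp = colnames(G), trait = tr, slope = NA_real_,
                      se = NA_real_, t = NA_real_, p = NA_real_,
                      n = NA_integer_, note = NA_character_,
                      stringsAsFactors = FALSE)
    if (!anyNA(Gb) && any(poly) && length(yb) >= 10L) {
      C <- cbind(1, cvb$age, cvb$sex, cvb$bmi)
      scan <- fwl_scan(Gb[, poly, drop = FALSE], yb, C)
      m <- match(scan$snp, res$snp)
      res$slope[m] <- scan$slope; res$se[m] <- scan$se
      res$t[m] <- scan$t; res$p[m] <- scan$p; res$n[m] <- scan$n
    } else {
      for (j in which(poly)) {
        f <- tryCatch(fit_additive(Gb[, j], yb, cvb), error = function(e) e)
        if (inherits(f, "error")) {
          res$note[j] <- conditionMessage(f)
        } else {
          res$slope[j] <- f$slope; res$se[j] <- f$se; res$t[j] <- f$t
          res$p[j] <- f$p; res$n[j] <- f$n
        }
      }
    }
    res$note[!poly] <- "monomorphic in analysis set"
    out[[ti]] <- res
  }
  do.call(rbind, out)
}
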