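#' SNP specifications for the genotype simulator
#'
#' @param id,chrom,pos identifier, chromosome label and 1-based position
#' @param maf minor allele frequency in (0, 0.5]
#' @param block optional LD-block label; SNPs sharing a label are drawn from
#'   a common haplotype pool (`NA` = unlinked singleton). The first SNP of
#'   each block (in input order) is the block lead.
#' @param r2_lead target r^2 of the SNP to its block lead, in \[0, 1\]
#'   (ignored for leads/singletons)
#' @param minor,major allele letters
#' @return data.frame of class `snp_spec`
#' @export
snp_spec <- function(id, chrom, pos, maf, block = NA_character_, r2_lead = 1,
                     minor = "A", major = "G") {
  d <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  pos = as.integer(pos), maf = as.numeric(maf),
                  block = as.character(block), r2_lead = as.numeric(r2_lead),
                  minor = minor, major = major, stringsAsFactors = FALSE)
  if (any(!(d$maf > 0 & d$maf <= 0.5)))
    stop("maf must lie in (0, 0.5]")
  if (any(!(d$r2_lead >= 0 & d$r2_lead <= 1)))
    stop("r2_lead must lie in [0, 1]")
  if (any(d$pos < 1)) stop("positions must be >= 1")
  class(d) <- c("snp_spec", "data.frame")
  d
}

#' Cohort configuration for the simulator
#'
#' Defaults emulate the KARE lipid cohort: 7795 subjects, 52.85% female,
#' mean age ~52 years, mean BMI ~24.6 kg/m^2.
#'
#' @param n_samples cohort size (>= 1)
#' @param sex_ratio fraction of female subjects (sex coded 0 = male,
#'   1 = female)
#' @param age_mean,age_sd age distribution, years
#' @param bmi_mean,bmi_sd BMI distribution, kg/m^2
#' @param hdl_mean,hdl_sd,hdl_floor HDL-c distribution, mg/dL (Gaussian
#'   truncated above `hdl_floor`)
#' @param missing_rate fraction of genotype calls masked as missing
#' @param seed master integer seed; all randomness derives from it
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_samples, sex_ratio = 0.5285, age_mean = 52.2,
                          age_sd = 8.9, bmi_mean = 24.6, bmi_sd = 3.1,
                          hdl_mean = 49, hdl_sd = 10, hdl_floor = 10,
                          missing_rate = 0, seed = 1L) {
  stopifnot(n_samples >= 1, sex_ratio >= 0, sex_ratio <= 1,
            age_sd >= 0, bmi_sd >= 0, hdl_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_samples = as.integer(n_samples), sex_ratio = sex_ratio,
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 hdl_mean = hdl_mean, hdl_sd = hdl_sd, hdl_floor = hdl_floor,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Trait effect model for the phenotype simulator
#'
#' @param effects data.frame with column `snp` and one column per trait
#'   giving the minor-allele slope (trait units per copy); may have zero rows
#' @param covar named list per trait of coefficients `c(age=, sex=, bmi=)`
#' @param intercepts named numeric, one per trait
#' @param sigma named numeric residual standard deviations per trait (> 0,
#'   or 0 for noise-free checks)
#' @return list of class `effect_model`
#' @export
effect_model <- function(effects, covar, intercepts, sigma) {
  traits <- names(intercepts)
  stopifnot(length(traits) >= 1, all(traits %in% names(covar)),
            all(traits %in% names(sigma)))
  if (any(unlist(sigma) < 0)) stop("residual sd must be >= 0")
  if (nrow(effects) && !all(traits %in% names(effects)))
    stop("effects table lacks a column for some trait")
  structure(list(effects = effects, covar = covar,
                 intercepts = intercepts, sigma = sigma, traits = traits),
            class = "effect_model")
}

#' Simulate a genotype panel with block LD structure
#'
#' Dosages are sums of two haplotype draws. Within a block, the lead SNP's
#' haplotype alleles are drawn Bernoulli(maf); a linked SNP copies the lead
#' allele with probability c = r * sqrt(m(1-m) / (p(1-p))) (r = sqrt of the
#' target r^2, p = lead MAF, m = linked MAF) and otherwise draws a fresh
#' allele with frequency chosen to preserve its MAF. This yields an
#' allele-level correlation of exactly r, hence pairwise r^2 approximating
#' the target; blocks are mutually independent. The same seed always yields
#' the same matrix.
#'
#' @param specs a [snp_spec()] data.frame (non-empty)
#' @param config a [cohort_config()]
#' @return a [genotype_matrix()]
#' @export
simulate_genotypes <- function(specs, config) {
  stopifnot(inherits(config, "cohort_config"), is.data.frame(specs),
            nrow(specs) >= 1)
  if (any(!(specs$maf > 0 & specs$maf <= 0.5)))
    stop("maf must lie in (0, 0.5]")
  n <- config$n_samples
  nh <- 2L * n
  block <- specs$block
  block[is.na(block)] <- paste0(".singleton", seq_len(sum(is.na(block))))
  ublocks <- unique(block)
  H <- matrix(0L, nh, nrow(specs))
  for (bi in seq_along(ublocks)) {
    members <- which(block == ublocks[bi])
    with_seed(derive_seed(config$seed, 1000L + bi), {
      lead <- members[1L]
      p <- specs$maf[lead]
      hl <- as.integer(runif(nh) < p)
      H[, lead] <- hl
      for (k in members[-1L]) {
        m <- specs$maf[k]
        r <- sqrt(specs$r2_lead[k])
        cc <- r * sqrt(m * (1 - m) / (p * (1 - p)))
        if (cc > 1 + 1e-12)
          stop("target r2 ", specs$r2_lead[k], " unattainable for MAFs ",
               p, " and ", m, " (SNP ", specs$id[k], ")")
        cc <- min(cc, 1)
        q <- if (cc < 1) (m - cc * p) / (1 - cc) else m
        if (q < -1e-12 || q > 1 + 1e-12)
          stop("target r2 ", specs$r2_lead[k], " unattainable for MAFs ",
               p, " and ", m, " (SNP ", specs$id[k], ")")
        q <- min(max(q, 0), 1)
        copy <- runif(nh) < cc
        fresh <- as.integer(runif(nh) < q)
        H[, k] <- ifelse(copy, hl, fresh)
      }
    })
  }
  d <- H[seq(1L, nh, by = 2L), , drop = FALSE] +
    H[seq(2L, nh, by = 2L), , drop = FALSE]
  if (config$missing_rate > 0) {
    with_seed(derive_seed(config$seed, 999331L), {
      mask <- runif(length(d)) < config$missing_rate
      d[mask] <- NA_integer_
    })
  }
  ids <- sprintf("S%05d", seq_len(n))
  genotype_matrix(d, specs[, c("id", "chrom", "pos", "minor", "major")], ids)
}

#' Simulate lipid phenotypes from genotypes and an effect model
#'
#' Each analysis trait is the linear predictor
#' intercept + sum_j slope_j * dosage_j + covariate terms + Gaussian noise on
#' the ratio scale. Sex is 0 = male / 1 = female, ages and BMI Gaussian.
#' Raw lipid columns are back-filled consistently with the ratios: HDL-c is
#' truncated Gaussian, TC = tc_hdl_ratio * HDL-c and
#' TG = 10^(log_tg_hdl_ratio * HDL-c), so re-deriving the traits from the
#' raw columns reproduces them exactly.
#'
#' @param genotypes a [genotype_matrix()]
#' @param effects an [effect_model()]
#' @param config a [cohort_config()]
#' @return phenotype data.frame (class `phenotype_table`) with raw and
#'   derived columns
#' @export
simulate_phenotypes <- function(genotypes, effects, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(effects, "effect_model"),
            inherits(config, "cohort_config"))
  n <- nrow(genotypes$dosage)
  causal <- effects$effects$snp
  absent <- setdiff(causal, genotypes$snps$id)
  if (length(absent))
    stop("causal SNP(s) absent from panel: ", paste(absent, collapse = ", "))
  G <- genotypes$dosage[, causal, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- mu[j]
  }
  with_seed(derive_seed(config$seed, 777001L), {
    sex <- rbinom(n, 1L, config$sex_ratio)      # 1 = female
    age <- rnorm(n, config$age_mean, config$age_sd)
    bmi <- rnorm(n, config$bmi_mean, config$bmi_sd)
    lo <- pnorm(config$hdl_floor, config$hdl_mean, config$hdl_sd)
    hdl <- qnorm(runif(n, lo, 1), config$hdl_mean, config$hdl_sd)
    traits <- list()
    for (tr in effects$traits) {
      b <- if (nrow(effects$effects)) effects$effects[[tr]] else numeric(0)
      cv <- effects$covar[[tr]]
      y <- effects$intercepts[[tr]] +
        (if (length(b)) drop(G %*% b) else 0) +
        cv[["age"]] * age + cv[["sex"]] * sex + cv[["bmi"]] * bmi +
        rnorm(n, 0, effects$sigma[[tr]])
      traits[[tr]] <- y
    }
  })
  tc_ratio <- traits[["tc_hdl_ratio"]]
  logtg_ratio <- traits[["log_tg_hdl_ratio"]]
  if (!is.null(tc_ratio) && any(tc_ratio <= 0)) {
    warning("clamped ", sum(tc_ratio <= 0), " non-positive TC/HDL-c ratio(s)")
    tc_ratio <- pmax(tc_ratio, 0.01)
  }
  ph <- data.frame(sample_id = genotypes$sample_ids, sex = sex, age = age,
                   bmi = bmi,
                   tc = if (!is.null(tc_ratio)) tc_ratio * hdl else NA_real_,
                   tg = if (!is.null(logtg_ratio)) 10^(logtg_ratio * hdl) else NA_real_,
                   hdl = hdl, stringsAsFactors = FALSE)
  build_traits(ph)
}

# Exact expected raw TG for the lognormal back-fill, integrating over the
# truncated-Gaussian HDL-c distribution: the ratio given sex is
# mu_det + genetic sum + N(0, v_env); E[TG | sex] =
# E_h[ 10^(mu_det h) * prod_j((1-m_j) + m_j 10^(h b_j))^2 * exp((ln10 h)^2 v_env / 2) ].
expected_tg <- function(mu_det, b, maf, v_env, hdl_mean, hdl_sd, hdl_floor) {
  l10 <- log(10)
  f <- function(h) {
    gen <- rep(1, length(h))
    for (j in seq_along(b))
      gen <- gen * ((1 - maf[j]) + maf[j] * exp(l10 * h * b[j]))^2
    dens <- dnorm(h, hdl_mean, hdl_sd) /
      (1 - pnorm(hdl_floor, hdl_mean, hdl_sd))
    exp(l10 * h * mu_det + (l10 * h)^2 * v_env / 2) * gen * dens
  }
  integrate(f, lower = hdl_floor, upper = hdl_mean + 8 * hdl_sd,
            rel.tol = 1e-9)$value
}

# Solve the deterministic part of the TG-ratio linear predictor so that the
# raw TG stratum mean matches `target` (e.g. 171.1 mg/dL for men).
calibrate_tg_mu <- function(target, b, maf, v_env, hdl_mean, hdl_sd,
                            hdl_floor) {
  uniroot(function(mu) expected_tg(mu, b, maf, v_env, hdl_mean, hdl_sd,
                                   hdl_floor) - target,
          interval = c(0.005, 0.08), tol = 1e-10)$root
}

#' Default effect model emulating the KARE cholesterol-ratio analysis
#'
#' Minor-allele slopes are the published selection-set regression slopes of
#' the six markers, signed by the direction of their per-genotype ratio
#' means (the risk allele is the major allele for rs12421652, rs17411126 and
#' rs16940212). Residual standard deviations are set by an a priori power
#' calculation: the weakest marker (rs10852765) should carry an expected
#' |t| of about 5.5 at n = 7016 so that the all-folds dual-trait selection
#' rule recovers every causal marker reliably. Since each marker is tested in
#' a single-SNP model, the other causal markers' (independent) contributions
#' count toward its error variance, so sigma solves
#' t = b sqrt(2 m (1-m) n) / sqrt(sigma^2 + v_bg) with v_bg the background
#' genetic variance, giving sigma = 0.52 for TC/HDL-c and 0.0065 for
#' log10(TG)/HDL-c. Covariate coefficients and
#' intercepts are calibrated so the simulated stratum means reproduce the
#' cohort's published clinical characteristics (TC/HDL-c ~4.15 men / ~3.92
#' women; raw TG means 171.1 men / 138.2 women via the exact lognormal
#' expectation).
#'
#' @param config a [cohort_config()] supplying the covariate and HDL-c
#'   distributions used in calibration
#' @param sigma_tc,sigma_logtg residual standard deviations per trait
#' @return an [effect_model()]
#' @export
kare_effect_model <- function(config = cohort_config(7795),
                              sigma_tc = 0.52, sigma_logtg = 0.0065) {
  ref <- kare_reference_snps()
  eff <- data.frame(snp = ref$marker,
                    tc_hdl_ratio = ref$trend_sign * ref$weight_tc_hdl,
                    log_tg_hdl_ratio = ref$trend_sign * ref$weight_log_tg_hdl,
                    stringsAsFactors = FALSE)
  covar <- list(
    tc_hdl_ratio = c(age = 0.002, sex = -0.232, bmi = 0.03),
    log_tg_hdl_ratio = c(age = 0.00003, sex = NA_real_, bmi = 0.0005))
  gen_mean <- colSums(eff[, -1L] * (2 * ref$maf))
  # TC/HDL-c: stratum means ~197.9/47.7 (men) and ~199.3/50.9 (women)
  target_tc_m <- 197.9 / 47.7
  target_tc_f <- 199.3 / 50.9
  b0_tc <- target_tc_m - covar$tc_hdl_ratio[["age"]] * config$age_mean -
    covar$tc_hdl_ratio[["bmi"]] * config$bmi_mean - gen_mean[["tc_hdl_ratio"]]
  covar$tc_hdl_ratio[["sex"]] <- target_tc_f - target_tc_m
  # TG: raw stratum means 171.1 (men) / 138.2 (women) via exact expectation
  v_env <- sigma_logtg^2 +
    (covar$log_tg_hdl_ratio[["age"]] * config$age_sd)^2 +
    (covar$log_tg_hdl_ratio[["bmi"]] * config$bmi_sd)^2
  b <- eff$log_tg_hdl_ratio
  mu_m <- calibrate_tg_mu(171.1, b, ref$maf, v_env, config$hdl_mean,
                          config$hdl_sd, config$hdl_floor)
  mu_f <- calibrate_tg_mu(138.2, b, ref$maf, v_env, config$hdl_mean,
                          config$hdl_sd, config$hdl_floor)
  covar$log_tg_hdl_ratio[["sex"]] <- mu_f - mu_m
  b0_tg <- mu_m - covar$log_tg_hdl_ratio[["age"]] * config$age_mean -
    covar$log_tg_hdl_ratio[["bmi"]] * config$bmi_mean
  effect_model(eff, covar,
               intercepts = c(tc_hdl_ratio = unname(b0_tc),
                              log_tg_hdl_ratio = unname(b0_tg)),
               sigma = c(tc_hdl_ratio = sigma_tc,
                         log_tg_hdl_ratio = sigma_logtg))
}

#' SNP specifications for the KARE-like panel
#'
#' The six causal markers (published positions, alleles and MAFs) as
#' mutually unlinked singleton blocks — the source analysis retained all six
#' after r^2 > 0.2 pruning, so they are unlinked in the cohort — plus 54
#' null SNPs arranged around the anchor positions in LD blocks of 4-5 with
#' within-block target r^2 between 0.3 and 0.6. Two null SNPs per anchor
#' region lie outside the +/-100 kb window to exercise the window filter.
#'
#' @return a [snp_spec()] data.frame (60 rows)
#' @export
kare_snp_specs <- function() {
  ref <- kare_reference_snps()
  causal <- snp_spec(ref$marker, ref$chrom, ref$pos, ref$maf,
                     block = paste0("causal_", ref$marker), r2_lead = 1,
                     minor = ref$minor, major = ref$major)
  offs <- c(-120000L, -80000L, -60000L, -40000L, 30000L, 50000L, 70000L,
            90000L, 130000L)
  r2s <- c(1, 0.5, 0.4, 0.3, 1, 0.6, 0.45, 0.35, 0.3)
  blk <- c("a", "a", "a", "a", "b", "b", "b", "b", "b")
  mafs <- c(0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.22, 0.18, 0.28)
  nulls <- do.call(rbind, lapply(seq_len(nrow(ref)), function(k) {
    snp_spec(sprintf("null_%s_%d", ref$marker[k], seq_along(offs)),
             ref$chrom[k], ref$pos[k] + offs,
             maf = pmin(0.5, mafs + 0.01 * k),
             block = paste0(ref$marker[k], "_", blk), r2_lead = r2s,
             minor = "C", major = "T")
  }))
  out <- rbind(causal, nulls)
  class(out) <- c("snp_spec", "data.frame")
  out
}

#' Synthetic KARE-like cohort fixture
#'
#' Generates a full synthetic cohort with the statistical structure of the
#' KARE cholesterol-ratio analysis: the six published markers at their
#' published MAFs and selection-set slopes, 54 null SNPs in LD blocks,
#' age/sex/BMI covariates matching the cohort's clinical characteristics,
#' and raw lipid columns back-filled from the simulated ratios. The anchor
#' list contains the six causal markers (they are GWAS catalogue markers or
#' perfect tags thereof).
#'
#' @param seed master integer seed
#' @param n cohort size, default 7795
#' @param effects optional [effect_model()] override
#' @return list with `genotypes`, `phenotypes`, `anchors` (data.frame
#'   rsid/chrom/pos), `causal` (the six marker ids), `effects`, `config`.
#' @export
kare_like_scenario <- function(seed, n = 7795L, effects = NULL) {
  config <- cohort_config(n, seed = seed)
  if (is.null(effects)) effects <- kare_effect_model(config)
  specs <- kare_snp_specs()
  genotypes <- simulate_genotypes(specs, config)
  phenotypes <- simulate_phenotypes(genotypes, effects, config)
  ref <- kare_reference_snps()
  anchors <- data.frame(rsid = ref$marker, chrom = ref$chrom, pos = ref$pos,
                        stringsAsFactors = FALSE)
  list(genotypes = genotypes, phenotypes = phenotypes, anchors = anchors,
       causal = ref$marker, effects = effects, config = config)
}
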