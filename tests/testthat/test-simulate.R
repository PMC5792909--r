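test_that("empirical MAF matches the specification within binomial error", {
  spec <- snp_spec("s1", "1", 100L, maf = 0.5)
  n <- 10000L
  g <- simulate_genotypes(spec, cohort_config(n, seed = 11))
  f <- mean(g$dosage) / 2
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / (2 * n)))
  # convergence: error shrinks roughly as 1/sqrt(n)
  errs <- sapply(c(500L, 50000L), function(nn) {
    gg <- simulate_genotypes(snp_spec("s1", "1", 100L, maf = 0.2),
                             cohort_config(nn, seed = 12))
    abs(mean(gg$dosage) / 2 - 0.2)
  })
  expect_lt(errs[2], 0.01)
})

test_that("genotype simulation is deterministic given the seed", {
  specs <- snp_spec(c("a", "b", "c"), "2", c(1L, 2L, 3L), c(0.3, 0.25, 0.5),
                    block = c("x", "x", NA), r2_lead = c(1, 0.4, 1))
  g1 <- simulate_genotypes(specs, cohort_config(500, seed = 99))
  g2 <- simulate_genotypes(specs, cohort_config(500, seed = 99))
  expect_identical(g1$dosage, g2$dosage)
  g3 <- simulate_genotypes(specs, cohort_config(500, seed = 100))
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("block LD hits its target r2, including the perfect-LD limit", {
  specs <- snp_spec(c("lead", "tag"), "1", c(1L, 2L), c(0.25, 0.25),
                    block = c("b", "b"), r2_lead = c(1, 1))
  g <- simulate_genotypes(specs, cohort_config(5000, seed = 5))
  expect_equal(em_haplotype_freqs(g$dosage[, 1], g$dosage[, 2])$r2, 1)

  for (target in c(0.3, 0.6)) {
    specs <- snp_spec(c("lead", "tag"), "1", c(1L, 2L), c(0.3, 0.22),
                      block = c("b", "b"), r2_lead = c(1, target))
    g <- simulate_genotypes(specs, cohort_config(6000, seed = 6))
    r2 <- em_haplotype_freqs(g$dosage[, 1], g$dosage[, 2])$r2
    expect_lt(abs(r2 - target), 0.1)
  }
})

test_that("SNPs in different blocks are independent", {
  specs <- snp_spec(c("a", "b"), "1", c(1L, 2L), c(0.3, 0.3),
                    block = c("b1", "b2"), r2_lead = c(1, 1))
  g <- simulate_genotypes(specs, cohort_config(10000, seed = 7))
  expect_lt(em_haplotype_freqs(g$dosage[, 1], g$dosage[, 2])$r2, 0.01)
})

test_that("invalid MAF and unattainable LD targets are rejected", {
  expect_error(snp_spec("s", "1", 1L, maf = 0), "maf")
  expect_error(snp_spec("s", "1", 1L, maf = 0.7), "maf")
  expect_error(
    simulate_genotypes(
      snp_spec(c("l", "t"), "1", c(1L, 2L), c(0.05, 0.5),
               block = c("b", "b"), r2_lead = c(1, 1)),
      cohort_config(100, seed = 1)),
    "unattainable")
})

test_that("zero effects, zero noise and zero covariates give a constant trait", {
  g <- tiny_panel(seed = 1, n = 50)
  eff <- effect_model(data.frame(snp = character(),
                                 tc_hdl_ratio = numeric(),
                                 log_tg_hdl_ratio = numeric()),
                      covar = list(tc_hdl_ratio = c(age = 0, sex = 0, bmi = 0),
                                   log_tg_hdl_ratio = c(age = 0, sex = 0, bmi = 0)),
                      intercepts = c(tc_hdl_ratio = 4.2, log_tg_hdl_ratio = 0.045),
                      sigma = c(tc_hdl_ratio = 0, log_tg_hdl_ratio = 0))
  ph <- simulate_phenotypes(g, eff, cohort_config(50, seed = 1))
  expect_equal(ph$tc_hdl_ratio, rep(4.2, 50))
  expect_equal(ph$log_tg_hdl_ratio, rep(0.045, 50))
})

test_that("noise-free phenotypes reproduce the linear predictor exactly", {
  g <- tiny_panel(seed = 3, n = 200)
  eff <- effect_model(data.frame(snp = c("snp1", "snp2"),
                                 tc_hdl_ratio = c(0.25, -0.1),
                                 log_tg_hdl_ratio = c(0.002, 0.001)),
                      covar = list(tc_hdl_ratio = c(age = 0.01, sex = -0.2, bmi = 0.03),
                                   log_tg_hdl_ratio = c(age = 0, sex = 0, bmi = 0)),
                      intercepts = c(tc_hdl_ratio = 3, log_tg_hdl_ratio = 0.04),
                      sigma = c(tc_hdl_ratio = 0, log_tg_hdl_ratio = 0))
  ph <- simulate_phenotypes(g, eff, cohort_config(200, seed = 3))
  pred <- 3 + 0.25 * g$dosage[, "snp1"] - 0.1 * g$dosage[, "snp2"] +
    0.01 * ph$age - 0.2 * ph$sex + 0.03 * ph$bmi
  expect_equal(ph$tc_hdl_ratio, unname(pred), tolerance = 1e-12)
  # raw columns are consistent with the ratios
  expect_equal(ph$tc / ph$hdl, ph$tc_hdl_ratio, tolerance = 1e-12)
  expect_equal(log10(ph$tg) / ph$hdl, ph$log_tg_hdl_ratio, tolerance = 1e-12)
})

test_that("unknown causal SNP ids are reported by name", {
  g <- tiny_panel(seed = 1, n = 50)
  eff <- effect_model(data.frame(snp = "rs_not_here", tc_hdl_ratio = 1,
                                 log_tg_hdl_ratio = 0),
                      covar = list(tc_hdl_ratio = c(age = 0, sex = 0, bmi = 0),
                                   log_tg_hdl_ratio = c(age = 0, sex = 0, bmi = 0)),
                      intercepts = c(tc_hdl_ratio = 1, log_tg_hdl_ratio = 1),
                      sigma = c(tc_hdl_ratio = 1, log_tg_hdl_ratio = 1))
  expect_error(simulate_phenotypes(g, eff, cohort_config(50, seed = 1)),
               "rs_not_here")
})

test_that("male-stratum raw TG mean is calibrated to 171.1 mg/dL", {
  sc <- kare_like_scenario(seed = 21, n = 5000)
  tg_m <- sc$phenotypes$tg[sc$phenotypes$sex == 0]
  se <- sd(tg_m) / sqrt(length(tg_m))
  expect_lt(abs(mean(tg_m) - 171.1), 3 * se)
})

test_that("OLS recovers a causal slope with nominal CI coverage", {
  # single causal SNP at the strongest published effect/MAF combination
  hits <- 0L
  for (s in 1:20) {
    specs <- snp_spec("rsX", "1", 1L, maf = 0.111)
    cfg <- cohort_config(2000, seed = 300 + s)
    g <- simulate_genotypes(specs, cfg)
    eff <- effect_model(data.frame(snp = "rsX", y = 0.239),
                        covar = list(y = c(age = 0.002, sex = -0.2, bmi = 0.03)),
                        intercepts = c(y = 3), sigma = c(y = 0.52))
    n <- 2000
    set.seed(1000 + s)
    ph <- data.frame(sample_id = g$sample_ids, sex = rbinom(n, 1, 0.5),
                     age = rnorm(n, 52, 9), bmi = rnorm(n, 24.6, 3))
    ph$y <- 3 + 0.239 * g$dosage[, 1] + 0.002 * ph$age - 0.2 * ph$sex +
      0.03 * ph$bmi + rnorm(n, 0, 0.52)
    f <- fit_additive(g$dosage[, 1], ph$y, ph)
    if (abs(f$slope - 0.239) <= qt(0.975, f$n - 5) * f$se) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("the KARE-like scenario has the published structure", {
  sc <- kare_like_scenario(seed = 9, n = 7795)
  expect_setequal(sc$causal,
                  c("rs4420638", "rs6589566", "rs12421652", "rs17411126",
                    "rs16940212", "rs10852765"))
  expect_true(all(sc$causal %in% sc$genotypes$snps$id))
  expect_gte(ncol(sc$genotypes$dosage) - 6L, 50L)  # null SNPs
  # causal MAFs near Table values
  ref <- kare_reference_snps()
  emp <- colMeans(sc$genotypes$dosage[, ref$marker]) / 2
  expect_lt(max(abs(emp - ref$maf)), 0.015)
  expect_lt(abs(emp[["rs4420638"]] - 0.111), 0.011)
  # anchors are the causal markers
  expect_setequal(sc$anchors$rsid, sc$causal)
})

test_that("null SNP slope estimates are centred on zero across seeds", {
  tstats <- sapply(1:20, function(s) {
    g <- tiny_panel(seed = s, n = 400, mafs = 0.3)
    ph <- null_phenotypes(g, seed = s)
    fit_additive(g$dosage[, 1], ph$y, ph)$t
  })
  expect_lt(abs(mean(tstats)), 3 / sqrt(20))
})
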