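make_assoc <- function(snps, slopes, trait = "tc_hdl_ratio") {
  data.frame(snp = snps, trait = trait, slope = slopes,
             se = 0.01, t = slopes / 0.01, p = 1e-6, n = 100,
             note = NA_character_, stringsAsFactors = FALSE)
}

test_that("risk alleles orient by slope sign and weights are magnitudes", {
  snps <- data.frame(id = c("a", "b", "c"), chrom = "1", pos = 1:3,
                     minor = c("G", "T", "C"), major = c("A", "G", "T"))
  assoc <- make_assoc(c("a", "b", "c"), c(0.239, -0.1, 0))
  w <- build_weights(assoc, c("a", "b", "c"), snps = snps)
  expect_equal(w$orientation, c("minor", "major", "minor"))
  expect_equal(w$weight, c(0.239, 0.1, 0))
  expect_equal(w$risk_allele, c("G", "G", "C"))
  expect_error(build_weights(assoc, c("a", "zzz")), "zzz")
})

test_that("wGRS is the weighted risk-allele count with published hand sums", {
  snps6 <- data.frame(id = paste0("m", 1:6), chrom = "1", pos = 1:6,
                      minor = "A", major = "G")
  # all six minor-oriented, dosage 2 everywhere: score = 2 * sum(weights)
  weights <- structure(
    data.frame(snp = paste0("m", 1:6), trait = "tc_hdl_ratio",
               orientation = "minor", risk_allele = "A",
               weight = c(0.239, 0.139, 0.118, 0.136, 0.079, 0.051),
               slope = c(0.239, 0.139, 0.118, 0.136, 0.079, 0.051)),
    class = c("grs_weights", "data.frame"))
  g2 <- genotype_matrix(matrix(2L, 1, 6), snps6, "s1")
  expect_equal(unname(compute_wgrs(g2, weights, "tc_hdl_ratio")), 1.524)
  g0 <- genotype_matrix(matrix(0L, 1, 6), snps6, "s1")
  expect_equal(unname(compute_wgrs(g0, weights, "tc_hdl_ratio")), 0)

  w1 <- structure(
    data.frame(snp = "m1", trait = "log_tg_hdl_ratio", orientation = "minor",
               risk_allele = "A", weight = 0.00249, slope = 0.00249),
    class = c("grs_weights", "data.frame"))
  g1 <- genotype_matrix(matrix(1L, 1, 6), snps6, "s1")
  expect_equal(unname(compute_wgrs(g1, w1, "log_tg_hdl_ratio")), 0.00249)
})

test_that("major-oriented weights flip the dosage scale", {
  snps <- data.frame(id = "a", chrom = "1", pos = 1L, minor = "G", major = "A")
  g <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1), snps,
                       c("s1", "s2", "s3"))
  assoc <- make_assoc("a", -0.1)
  w <- build_weights(assoc, "a", snps = snps)
  sc <- compute_wgrs(g, w, "tc_hdl_ratio")
  expect_equal(unname(sc), c(0.2, 0.1, 0))   # risk count = 2 - dosage
})

test_that("wGRS is additive over weight sets and invariant to relabeling", {
  g <- tiny_panel(seed = 40, n = 50)
  assoc <- make_assoc(paste0("snp", 1:4), c(0.3, -0.2, 0.1, 0.05))
  w_all <- build_weights(assoc, paste0("snp", 1:4), snps = g$snps)
  w_a <- build_weights(assoc, paste0("snp", 1:2), snps = g$snps)
  w_b <- build_weights(assoc, paste0("snp", 3:4), snps = g$snps)
  expect_equal(compute_wgrs(g, w_all, "tc_hdl_ratio"),
               compute_wgrs(g, w_a, "tc_hdl_ratio") +
                 compute_wgrs(g, w_b, "tc_hdl_ratio"))
  # consistent relabeling: flip orientation AND dosage -> same scores
  w_flip <- w_all
  w_flip$orientation <- ifelse(w_all$orientation == "minor", "major", "minor")
  gf <- genotype_matrix(2L - g$dosage, g$snps, g$sample_ids)
  expect_equal(compute_wgrs(gf, w_flip, "tc_hdl_ratio"),
               compute_wgrs(g, w_all, "tc_hdl_ratio"))
})

test_that("missing genotypes are mean-imputed with a message", {
  snps <- data.frame(id = "a", chrom = "1", pos = 1L, minor = "G", major = "A")
  g <- genotype_matrix(matrix(c(0L, 2L, NA), 3, 1), snps, c("s1", "s2", "s3"))
  w <- build_weights(make_assoc("a", 0.5), "a", snps = snps)
  expect_message(sc <- compute_wgrs(g, w, "tc_hdl_ratio"), "imputed")
  expect_equal(unname(sc[3]), 0.5 * 1)   # mean dosage of s1/s2 is 1
  expect_error(compute_wgrs(g, w, "log_tg_hdl_ratio"), "no weights")
})

test_that("quartile binning is rank-based, stable and equal-count", {
  expect_equal(quartile_bin(c(1, 2, 3, 4)), 1:4)
  expect_equal(quartile_bin(1:8), rep(1:4, each = 2))
  expect_equal(quartile_bin(c(5, 1, 9, 3)), c(3L, 1L, 4L, 2L))
  labs <- quartile_bin(rep(7, 10))
  expect_lte(diff(range(table(labs))), 1L)
  expect_equal(labs[1:2], c(1L, 1L))   # stable: early rows get low quartiles
  expect_error(quartile_bin(1:3), "4")
})

test_that("trend_fit handles exact, null and degenerate inputs", {
  labs <- rep(1:4, each = 25)
  exact <- as.numeric(labs) * 2 + 1
  t1 <- trend_fit(exact, labs)
  expect_equal(t1$r_squared, 1)
  expect_equal(t1$r_squared_individual, 1)
  expect_equal(t1$slope, 2)
  expect_equal(t1$quartile_means, c(3, 5, 7, 9))

  set.seed(50)
  t2 <- trend_fit(rnorm(400), quartile_bin(rnorm(400)))
  expect_lt(abs(t2$slope), 0.2)
  expect_lt(t2$r_squared_individual, 0.02)

  expect_error(trend_fit(1:6, c(1, 1, 2, 2, 4, 4)), "empty quartile")
})

test_that("holdout evaluation reuses training weights unchanged", {
  sc <- kare_like_scenario(seed = 51, n = 2000)
  g <- sc$genotypes; ph <- sc$phenotypes
  res <- evaluate_holdout(g, ph, g, ph, selected = sc$causal)
  # holdout == training: trend must equal the in-sample trend of those weights
  w <- attr(res, "weights")
  sc_tc <- compute_wgrs(g, w, "tc_hdl_ratio")
  direct <- trend_fit(sc_tc, quartile_bin(ph$tc_hdl_ratio))
  expect_equal(res$tc_hdl_ratio$all$quartile_means, direct$quartile_means,
               tolerance = 1e-12)
  expect_true(all(c("all", "male", "female") %in% names(res$tc_hdl_ratio)))
})

test_that("a null-effect simulation gives a flat holdout trend", {
  g <- tiny_panel(seed = 52, n = 1500)
  ph <- null_phenotypes(g, seed = 52)
  ph$tc <- 150 + 10 * ph$y; ph$hdl <- 50; ph$tg <- 120
  ph <- build_traits(ph)
  idx_tr <- 1:1000; idx_ho <- 1001:1500
  gtr <- subset_genotypes(g, samples = g$sample_ids[idx_tr])
  gho <- subset_genotypes(g, samples = g$sample_ids[idx_ho])
  res <- evaluate_holdout(gtr, ph[idx_tr, ], gho, ph[idx_ho, ],
                          selected = c("snp1", "snp2"))
  tr <- res$tc_hdl_ratio$all
  expect_lt(abs(tr$slope), 0.05)
  expect_gt(tr$p_value, 1e-4)
})

test_that("grs_fit returns a working model object", {
  sc <- kare_like_scenario(seed = 53, n = 2500)
  fit <- suppressWarnings(grs_fit(sc$genotypes, sc$phenotypes,
                                  candidates = sc$causal, seed = 53))
  expect_s3_class(fit, "grs_fit")
  expect_output(print(fit), "risk score")
  expect_output(print(summary(fit)), "quartile trends")
  if (length(fit$selection$selected)) {
    cw <- coef(fit)
    expect_true(is.matrix(cw))
    expect_equal(colnames(cw), c("tc_hdl_ratio", "log_tg_hdl_ratio"))
    pr <- predict(fit, newdata = sc$genotypes, trait = "tc_hdl_ratio")
    expect_equal(pr[names(fit$scores$tc_hdl_ratio)], fit$scores$tc_hdl_ratio)
    path <- tempfile(fileext = ".png")
    grDevices::png(path); plot(fit); grDevices::dev.off()
    expect_true(file.exists(path))
  }
})
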