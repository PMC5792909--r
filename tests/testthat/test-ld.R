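test_that("identical loci are in perfect LD and independent loci are not", {
  set.seed(1)
  g <- sample(0:2, 500, TRUE)
  expect_equal(em_haplotype_freqs(g, g)$r2, 1, tolerance = 1e-9)
  a <- rbinom(10000, 2, 0.3); b <- rbinom(10000, 2, 0.4)
  expect_lt(em_haplotype_freqs(a, b)$r2, 0.01)
})

test_that("EM equals exhaustive grid-search likelihood maximization", {
  set.seed(7)
  for (k in 1:40) {
    tab <- random_genotype_table(400)
    d <- table_to_dosages(tab)
    em <- em_haplotype_freqs(d$g1, d$g2)
    oracle <- grid_search_haplotypes(tab)
    expect_lt(max(abs(em$haplotype_freqs - oracle)), 1e-6)
  }
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(3)
  for (k in 1:20) {
    tab <- random_genotype_table(300)
    d <- table_to_dosages(tab)
    r_ab <- em_haplotype_freqs(d$g1, d$g2)$r2
    r_ba <- em_haplotype_freqs(d$g2, d$g1)$r2
    r_flip1 <- em_haplotype_freqs(2L - d$g1, d$g2)$r2
    r_flip2 <- em_haplotype_freqs(d$g1, 2L - d$g2)$r2
    expect_equal(r_ab, r_ba, tolerance = 1e-9)
    expect_equal(r_ab, r_flip1, tolerance = 1e-8)
    expect_equal(r_ab, r_flip2, tolerance = 1e-8)
  }
})

test_that("monomorphic loci and length mismatches are rejected", {
  expect_error(em_haplotype_freqs(rep(0, 50), sample(0:2, 50, TRUE)),
               "monomorphic")
  expect_error(em_haplotype_freqs(0:1, 0:2), "length")
})

test_that("missing genotypes are handled pairwise-complete", {
  set.seed(11)
  a <- rbinom(300, 2, 0.3); b <- rbinom(300, 2, 0.3)
  a2 <- a; a2[1:20] <- NA
  r <- em_haplotype_freqs(a2, b)
  expect_equal(r$n, 280)
  ref <- em_haplotype_freqs(a[21:300], b[21:300])
  expect_equal(r$r2, ref$r2, tolerance = 1e-12)
})

test_that("anchor windows are inclusive, chromosome-aware and deduplicated", {
  snps <- data.frame(id = c("in_edge", "out", "wrong_chr", "dup"),
                     chrom = c("1", "1", "2", "1"),
                     pos = c(200000L, 220001L, 100000L, 150000L),
                     minor = "A", major = "G")
  anchors <- data.frame(rsid = c("a1", "a2"), chrom = c("1", "1"),
                        pos = c(100000L, 120000L))
  out <- window_filter(snps, anchors, window_bp = 100000L)
  expect_setequal(out$id, c("in_edge", "dup"))   # 100 kb boundary kept; union once
  expect_false("wrong_chr" %in% out$id)
})

test_that("greedy pruning respects priorities and its r2 post-condition", {
  # two SNPs in perfect LD: only the higher-priority one survives
  specs <- snp_spec(c("lead", "copy"), "1", c(1L, 2L), c(0.3, 0.3),
                    block = c("b", "b"), r2_lead = c(1, 1))
  g <- simulate_genotypes(specs, cohort_config(800, seed = 13))
  kept <- prune_by_ld(g$snps, g, r2_max = 0.2,
                      priority = c(lead = 2, copy = 1))
  expect_equal(kept$id, "lead")
  kept2 <- prune_by_ld(g$snps, g, r2_max = 0.2,
                       priority = c(lead = 1, copy = 2))
  expect_equal(kept2$id, "copy")

  # independent SNPs all survive
  g2 <- tiny_panel(seed = 14, n = 800)
  expect_equal(nrow(prune_by_ld(g2$snps, g2)), nrow(g2$snps))

  # 10-SNP correlated block: verify the kept set's pairwise r2 directly
  specs <- snp_spec(paste0("s", 1:10), "1", 1:10, rep(0.3, 10),
                    block = "blk", r2_lead = c(1, seq(0.9, 0.1, length.out = 9)))
  g3 <- simulate_genotypes(specs, cohort_config(3000, seed = 15))
  kept3 <- prune_by_ld(g3$snps, g3, r2_max = 0.2)
  if (nrow(kept3) > 1) {
    r2 <- ld_r2_matrix(g3, kept3$id)
    expect_lte(max(r2[upper.tri(r2)]), 0.2)
  }
})

test_that("pruning output is invariant to input order given fixed priorities", {
  specs <- snp_spec(paste0("s", 1:8), "1", 1:8, rep(0.25, 8),
                    block = "blk", r2_lead = c(1, seq(0.8, 0.2, length.out = 7)))
  g <- simulate_genotypes(specs, cohort_config(2000, seed = 16))
  pri <- setNames(seq(8, 1), paste0("s", 1:8))
  a <- prune_by_ld(g$snps, g, priority = pri)
  perm <- g$snps[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  b <- prune_by_ld(perm, g, priority = pri)
  expect_setequal(a$id, b$id)
})

test_that("tag-SNP linking keeps anchors and tight proxies only", {
  specs <- snp_spec(c("anchor", "proxy", "weak"), "1", c(1L, 2L, 3L),
                    c(0.3, 0.3, 0.3), block = c("b", "b", "b"),
                    r2_lead = c(1, 1, 0.5))
  g <- simulate_genotypes(specs, cohort_config(4000, seed = 17))
  anchors <- data.frame(rsid = "anchor", chrom = "1", pos = 1L)
  out <- link_to_anchors(g$snps, g, anchors, r2_min = 0.98)
  expect_true("anchor" %in% out$id)
  expect_true("proxy" %in% out$id)
  expect_false("weak" %in% out$id)
  # absent anchor: warning, not error
  anchors2 <- rbind(anchors, data.frame(rsid = "ghost", chrom = "9", pos = 5L))
  expect_warning(link_to_anchors(g$snps, g, anchors2), "ghost")
})

test_that("LD blocks are the connected components of the r2 > 0.2 graph", {
  specs <- rbind(
    snp_spec(c("a1", "a2"), "1", c(1L, 2L), c(0.3, 0.3), block = c("A", "A"),
             r2_lead = c(1, 0.8)),
    snp_spec(c("b1", "b2"), "1", c(100L, 101L), c(0.25, 0.25),
             block = c("B", "B"), r2_lead = c(1, 0.7)),
    snp_spec("solo", "2", 5L, 0.4))
  g <- simulate_genotypes(specs, cohort_config(3000, seed = 18))
  blocks <- ld_blocks(g)
  expect_equal(blocks[["a1"]], blocks[["a2"]])
  expect_equal(blocks[["b1"]], blocks[["b2"]])
  expect_false(blocks[["a1"]] == blocks[["b1"]])
  expect_false(blocks[["solo"]] %in% blocks[c("a1", "b1")])
})
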