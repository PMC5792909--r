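# Independent oracles used by the LD tests. Everything here is deliberately
# separate from the package's EM code path: the likelihood is maximized by
# brute-force grid search over the single free haplotype frequency.

# Multinomial log-likelihood of a 3x3 genotype count table under haplotype
# frequencies (mm, mM, Mm, MM); rows = dosage at locus 1.
genotype_loglik <- function(tab, h_mm, pA, pB) {
  h_mM <- pA - h_mm
  h_Mm <- pB - h_mm
  h_MM <- 1 - pA - pB + h_mm
  P <- rbind(
    c(h_MM^2,          2 * h_Mm * h_MM,                 h_Mm^2),
    c(2 * h_mM * h_MM, 2 * (h_mm * h_MM + h_mM * h_Mm), 2 * h_mm * h_Mm),
    c(h_mM^2,          2 * h_mm * h_mM,                 h_mm^2))
  ll <- 0
  for (i in 1:3) for (j in 1:3) {
    if (tab[i, j] > 0) {
      if (P[i, j] <= 0) return(-Inf)
      ll <- ll + tab[i, j] * log(P[i, j])
    }
  }
  ll
}

# Exhaustive grid maximization of the two-locus likelihood over the
# coupling-haplotype frequency, marginal allele frequencies held at their
# sample values (they are determined by the genotype counts). Coarse pass at
# step 1e-5 followed by a fine pass at 1e-8 around the optimum.
grid_search_haplotypes <- function(tab) {
  n <- sum(tab)
  pA <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = 1e-5)
  ll <- vapply(grid, genotype_loglik, 0, tab = tab, pA = pA, pB = pB)
  best <- grid[which.max(ll)]
  fine <- seq(max(lo, best - 2e-5), min(hi, best + 2e-5), by = 1e-8)
  llf <- vapply(fine, genotype_loglik, 0, tab = tab, pA = pA, pB = pB)
  h_mm <- fine[which.max(llf)]
  c(mm = h_mm, mM = pA - h_mm, Mm = pB - h_mm, MM = 1 - pA - pB + h_mm)
}

# Random polymorphic two-locus genotype table: draw haplotype frequencies
# with both allele frequencies in [0.05, 0.95], then n diploid genotypes.
random_genotype_table <- function(n = 400) {
  repeat {
    h <- as.numeric(stats::rexp(4) + 0.02)
    h <- h / sum(h)
    pA <- h[1] + h[2]; pB <- h[1] + h[3]
    if (pA > 0.05 && pA < 0.95 && pB > 0.05 && pB < 0.95) break
  }
  hap <- sample.int(4, 2 * n, replace = TRUE, prob = h)
  a <- as.integer(hap %in% c(1L, 2L))   # minor allele at locus 1
  b <- as.integer(hap %in% c(1L, 3L))   # minor allele at locus 2
  g1 <- a[seq(1, 2 * n, 2)] + a[seq(2, 2 * n, 2)]
  g2 <- b[seq(1, 2 * n, 2)] + b[seq(2, 2 * n, 2)]
  tab <- matrix(tabulate(3L * g1 + g2 + 1L, nbins = 9L), 3L, 3L, byrow = TRUE)
  # re-draw if a locus came out monomorphic
  if (sum(tab * matrix(0:2, 3, 3)) %in% c(0, 2 * n) ||
      sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) %in% c(0, 2 * n))
    return(random_genotype_table(n))
  tab
}

# Dosage pair with a given genotype table (for feeding the exported EM
# interface rather than the internal table form).
table_to_dosages <- function(tab) {
  g1 <- integer(0); g2 <- integer(0)
  for (i in 0:2) for (j in 0:2) {
    k <- tab[i + 1, j + 1]
    g1 <- c(g1, rep.int(i, k)); g2 <- c(g2, rep.int(j, k))
  }
  list(g1 = g1, g2 = g2)
}
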