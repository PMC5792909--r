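#' Two-locus haplotype frequencies and r-squared by EM
#'
#' Estimates the four two-locus haplotype frequencies from unphased dosage
#' vectors by expectation-maximization over the double-heterozygote phase
#' ambiguity, then computes the linkage-disequilibrium coefficient
#' r^2 = D^2 / (pA (1 - pA) pB (1 - pB)) with D = p_mm - pA * pB, where `mm`
#' is the haplotype carrying the minor allele at both loci.
#'
#' Every genotype class except the double heterozygote resolves into
#' haplotypes unambiguously; the EM iterates the expected split of the double
#' heterozygotes between the coupling (mm/MM) and repulsion (mM/Mm) phases.
#' Missing genotypes are handled by pairwise-complete deletion.
#' Initialization is at linkage equilibrium, and iteration stops when the
#' largest haplotype-frequency change falls below `tol` (default 1e-9) or
#' after `max_iter` iterations.
#'
#' @param dosage_i,dosage_j minor-allele dosage vectors in \{0,1,2,NA\} of
#'   equal length.
#' @param snp_i,snp_j optional SNP identifiers carried into the result.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter maximum EM iterations.
#' @return An object of class `ld_pair`: list with `snp_i`, `snp_j`,
#'   `haplotype_freqs` (named `mm`, `mM`, `Mm`, `MM`; m = minor allele),
#'   `r2`, `D`, `n` (pairwise-complete sample count), `iterations`,
#'   `converged`.
#' @examples
#' g <- c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2)
#' em_haplotype_freqs(g, g)$r2  # 1: identical loci are in perfect LD
#' @export
em_haplotype_freqs <- function(dosage_i, dosage_j, snp_i = NA_character_,
                               snp_j = NA_character_, tol = 1e-9,
                               max_iter = 1000L) {
  if (length(dosage_i) != length(dosage_j))
    stop("dosage vectors differ in length")
  keep <- !is.na(dosage_i) & !is.na(dosage_j)
  gi <- dosage_i[keep]; gj <- dosage_j[keep]
  if (!length(gi)) stop("no pairwise-complete genotypes")
  tab <- matrix(tabulate(3L * gi + gj + 1L, nbins = 9L), 3L, 3L, byrow = TRUE)
  em_from_table(tab, snp_i = snp_i, snp_j = snp_j, tol = tol,
                max_iter = max_iter)
}

# EM on a 3x3 genotype count table; rows = dosage at locus i (0,1,2),
# columns = dosage at locus j.
em_from_table <- function(tab, snp_i = NA_character_, snp_j = NA_character_,
                          tol = 1e-9, max_iter = 1000L) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(3L, 3L)), all(tab >= 0))
  n <- sum(tab)
  pA <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)        # minor freq locus i
  pB <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("r2 undefined: monomorphic locus")
  # deterministic haplotype counts (double het n[2,2] handled in the loop)
  c_mm0 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  c_mM0 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
  c_Mm0 <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2]
  c_MM0 <- 2 * tab[1, 1] + tab[2, 1] + tab[1, 2]
  ndh <- tab[2, 2]
  h <- c(mm = pA * pB, mM = pA * (1 - pB), Mm = (1 - pA) * pB,
         MM = (1 - pA) * (1 - pB))
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    coup <- unname(h["mm"] * h["MM"])
    rep_ <- unname(h["mM"] * h["Mm"])
    a <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    h_new <- c(mm = c_mm0 + a * ndh,
               mM = c_mM0 + (1 - a) * ndh,
               Mm = c_Mm0 + (1 - a) * ndh,
               MM = c_MM0 + a * ndh) / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  D <- unname(h["mm"] - pA * pB)
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(snp_i = snp_i, snp_j = snp_j,
                 haplotype_freqs = h, r2 = unname(r2), D = D, n = n,
                 iterations = it, converged = converged),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair %s ~ %s: r2 = %.4f (n = %d, %d EM iterations)\n",
              x$snp_i, x$snp_j, x$r2, x$n, x$iterations))
  cat("  haplotype freqs:",
      paste(names(x$haplotype_freqs),
            sprintf("%.4f", x$haplotype_freqs), sep = "=", collapse = " "), "\n")
  invisible(x)
}

# All pairwise 3x3 genotype tables for the SNP columns in `d` (a dosage
# matrix), via indicator-matrix crossproducts; returns a function
# table(i, j) -> 3x3 count matrix. Missing entries are excluded pairwise.
pairwise_table_fn <- function(d) {
  ind <- lapply(0:2, function(a) {
    m <- (!is.na(d)) & (d == a)
    storage.mode(m) <- "double"
    m
  })
  cp <- vector("list", 9L)
  for (a in 0:2) for (b in 0:2)
    cp[[3L * a + b + 1L]] <- crossprod(ind[[a + 1L]], ind[[b + 1L]])
  function(i, j) {
    t(vapply(0:2, function(a)
      vapply(0:2, function(b) cp[[3L * a + b + 1L]][i, j], 0), numeric(3)))
  }
}

#' Pairwise r-squared matrix for a set of SNPs
#'
#' Computes EM-based r^2 between every pair of the requested SNPs.
#' Cross-chromosome pairs are set to 0 without estimation (unlinked loci).
#'
#' @param genotypes a [genotype_matrix()]
#' @param ids SNP ids to include (default: all)
#' @return symmetric numeric matrix of r^2 with SNP ids as dimnames.
#' @export
ld_r2_matrix <- function(genotypes, ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(ids)) ids <- genotypes$snps$id
  idx <- match(ids, genotypes$snps$id)
  if (anyNA(idx)) stop("unknown SNP id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  d <- genotypes$dosage[, idx, drop = FALSE]
  chrom <- genotypes$snps$chrom[idx]
  p <- length(ids)
  tabfn <- pairwise_table_fn(d)
  out <- matrix(0, p, p, dimnames = list(ids, ids))
  if (p >= 2L) {
    for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
      if (chrom[i] != chrom[j]) next
      out[i, j] <- out[j, i] <- em_from_table(tabfn(i, j))$r2
    }
  }
  diag(out) <- 1
  out
}

#' Restrict SNPs to windows around GWAS anchor markers
#'
#' Keeps SNPs lying on an anchor's chromosome within `window_bp` base pairs
#' of the anchor position (boundary inclusive), taking the union over all
#' anchors; anchors present in the SNP list are always kept.
#'
#' @param snps data.frame of SNP records (columns `id`, `chrom`, `pos`, ...)
#' @param anchors data.frame with columns `rsid`, `chrom`, `pos`
#' @param window_bp half-window size in bp, default 100000 (i.e. +/-100 kb)
#' @return the filtered `snps` data.frame (each SNP reported once)
#' @export
window_filter <- function(snps, anchors, window_bp = 100000L) {
  stopifnot(is.data.frame(snps), is.data.frame(anchors))
  keep <- snps$id %in% anchors$rsid
  for (k in seq_len(nrow(anchors))) {
    keep <- keep | (snps$chrom == as.character(anchors$chrom[k]) &
                      abs(snps$pos - anchors$pos[k]) <= window_bp)
  }
  snps[keep, , drop = FALSE]
}

#' Greedy LD pruning
#'
#' Visits SNPs in descending priority (ties broken by lower genomic
#' coordinate) and keeps a SNP iff its EM r^2 with every already-kept SNP on
#' the same chromosome is at most `r2_max`, so that no retained pair exceeds
#' the threshold. With association p-values available, use
#' `priority = -log10(p)` so the most significant member of each correlated
#' group survives; the default priority is the SNP's MAF.
#'
#' @param snps data.frame of SNP records to prune
#' @param genotypes a [genotype_matrix()] containing all `snps`
#' @param r2_max maximum allowed pairwise r^2 among kept SNPs (default 0.2)
#' @param priority optional numeric vector (same length/order as `snps` rows
#'   or named by SNP id); larger values are kept preferentially.
#' @return the retained subset of `snps`, in original row order.
#' @export
prune_by_ld <- function(snps, genotypes, r2_max = 0.2, priority = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), is.data.frame(snps))
  idx <- match(snps$id, genotypes$snps$id)
  if (anyNA(idx)) stop("SNP(s) absent from genotypes: ",
                       paste(snps$id[is.na(idx)], collapse = ", "))
  if (is.null(priority)) {
    priority <- snps$maf
    if (is.null(priority) || anyNA(priority)) {
      f <- colMeans(genotypes$dosage[, idx, drop = FALSE], na.rm = TRUE) / 2
      priority <- pmin(f, 1 - f)
    }
  } else if (!is.null(names(priority))) {
    priority <- priority[snps$id]
  }
  if (length(priority) != nrow(snps)) stop("priority length mismatch")
  ord <- order(-priority, snps$chrom, snps$pos, snps$id)
  d <- genotypes$dosage
  kept <- integer(0)  # row indices of `snps`
  for (k in ord) {
    ok <- TRUE
    for (m in kept) {
      if (snps$chrom[m] != snps$chrom[k]) next
      r2 <- em_haplotype_freqs(d[, idx[k]], d[, idx[m]])$r2
      if (r2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, k)
  }
  snps[sort(kept), , drop = FALSE]
}

#' Keep SNPs tag-linked to GWAS anchor markers
#'
#' Retains SNPs that either are an anchor themselves or have EM r^2 of at
#' least `r2_min` with at least one genotyped anchor on the same chromosome.
#' Anchors absent from the genotype panel are skipped with a warning.
#'
#' @param snps data.frame of SNP records
#' @param genotypes a [genotype_matrix()]
#' @param anchors data.frame with columns `rsid`, `chrom`, `pos`
#' @param r2_min minimum r^2 to an anchor, default 0.98
#' @return the retained subset of `snps`
#' @export
link_to_anchors <- function(snps, genotypes, anchors, r2_min = 0.98) {
  stopifnot(inherits(genotypes, "genotype_matrix"), is.data.frame(snps))
  present <- anchors$rsid %in% genotypes$snps$id
  if (any(!present))
    warning("anchor(s) absent from genotype panel, skipped: ",
            paste(anchors$rsid[!present], collapse = ", "))
  anchors_g <- anchors[present, , drop = FALSE]
  d <- genotypes$dosage
  aidx <- match(anchors_g$rsid, genotypes$snps$id)
  achrom <- genotypes$snps$chrom[aidx]
  keep <- logical(nrow(snps))
  sidx <- match(snps$id, genotypes$snps$id)
  for (k in seq_len(nrow(snps))) {
    if (snps$id[k] %in% anchors$rsid) { keep[k] <- TRUE; next }
    if (is.na(sidx[k])) next
    for (a in seq_along(aidx)) {
      if (achrom[a] != snps$chrom[k]) next
      r2 <- em_haplotype_freqs(d[, sidx[k]], d[, aidx[a]])$r2
      if (r2 >= r2_min) { keep[k] <- TRUE; break }
    }
  }
  snps[keep, , drop = FALSE]
}

#' LD blocks as connected components of the r^2 graph
#'
#' Builds the graph whose vertices are the requested SNPs and whose edges
#' join pairs with r^2 above `r2_threshold`, and labels each SNP with its
#' connected component. This is the "same LD" structure used by the
#' cross-validation selection rule (one representative per block per fold).
#'
#' @param genotypes a [genotype_matrix()]
#' @param ids SNP ids (default: all)
#' @param r2_threshold edge threshold, default 0.2
#' @param r2 optional precomputed r^2 matrix from [ld_r2_matrix()]
#' @return named integer vector mapping SNP id to block label
#' @export
ld_blocks <- function(genotypes, ids = NULL, r2_threshold = 0.2, r2 = NULL) {
  if (is.null(ids)) ids <- genotypes$snps$id
  if (is.null(r2)) r2 <- ld_r2_matrix(genotypes, ids)
  adj <- (r2 > r2_threshold)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), ids)
}
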