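# Small programmatic fixtures shared across test files.

# Independent-SNP genotype panel for QC/association tests.
tiny_panel <- function(seed = 42, n = 600, mafs = c(0.3, 0.2, 0.4, 0.25, 0.35)) {
  specs <- snp_spec(paste0("snp", seq_along(mafs)), chrom = "1",
                    pos = seq(100L, by = 100L, length.out = length(mafs)),
                    maf = mafs)
  simulate_genotypes(specs, cohort_config(n, seed = seed))
}

# Covariates + a trait with no genetic signal.
null_phenotypes <- function(genotypes, seed = 1, sigma = 1) {
  n <- length(genotypes$sample_ids)
  set.seed(seed)
  data.frame(sample_id = genotypes$sample_ids,
             sex = rbinom(n, 1, 0.5), age = rnorm(n, 52, 9),
             bmi = rnorm(n, 24.6, 3), y = rnorm(n, 0, sigma),
             stringsAsFactors = FALSE)
}

mini_vcf_lines <- function(records, samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

write_lines_tmp <- function(lines, ext = ".vcf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Phenotype data.frame with exact raw lipid values.
mini_phenotypes <- function(n = 6) {
  data.frame(sample_id = sprintf("s%d", seq_len(n)),
             sex = rep_len(c(0, 1), n),
             age = seq(45, length.out = n),
             bmi = seq(22, length.out = n, by = 0.5),
             tc = rep_len(c(200, 180, 220), n),
             tg = rep_len(c(100, 150, 162), n),
             hdl = rep_len(c(50, 45, 49), n),
             stringsAsFactors = FALSE)
}
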