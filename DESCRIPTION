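Package: lipidgrs
Title: Weighted Genetic Risk Scores for Cholesterol-Ratio Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates weighted genetic risk scores (wGRS) for the
    blood cholesterol ratios TC/HDL-c and log10(TG)/HDL-c from biallelic SNP
    genotypes. Implements genotype quality control (call rate, minor allele
    frequency), two-locus haplotype-frequency estimation by
    expectation-maximization with r-squared linkage-disequilibrium pruning and
    anchor tag-SNP linking, per-SNP additive linear regression with age, sex
    and BMI covariates, k-fold cross-validation consistency SNP selection, and
    quartile trend evaluation of the resulting scores. A synthetic cohort
    generator reproduces the statistical structure of the Korea Association
    Resource (KARE) lipid analysis so the whole pipeline is testable without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
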