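# lipidgrs

Weighted genetic risk scores (wGRS) for blood cholesterol ratios.

Cholesterol ratios — total cholesterol over HDL cholesterol (TC/HDL-c) and
triglyceride over HDL cholesterol (TG/HDL-c) — are strong indicators of
cardiovascular and metabolic risk. This package implements, end to end, the
analysis design used to build a six-SNP prediction panel for these ratios in
the Korea Association Resource (KARE) cohort: genotype quality control, a
linkage-disequilibrium cascade around published GWAS anchor markers,
per-SNP additive regression with clinical covariates, 10-fold
cross-validation consistency selection, and quartile-trend evaluation of the
resulting risk scores. It is aimed at statistical geneticists who want a
tested, reproducible implementation of this wGRS workflow — and, because the
KARE genotypes are access-controlled, it ships a synthetic cohort generator
that reproduces the published statistical structure so the whole pipeline
can be exercised at realistic scale.

## The method

For each SNP *i* and each trait (TC/HDL-c and log10(TG)/HDL-c), an additive
model is fitted by ordinary least squares:

    trait = b0 + b_i * dosage_i + c1*age + c2*sex + c3*BMI + e

Candidate SNPs pass a ±100 kb window around GWAS anchors, greedy pruning at
r² > 0.2 (r² from EM-estimated two-locus haplotype frequencies), and
tag-linking to anchors at r² ≥ 0.98. The selection cohort is split into
k = 10 folds; a SNP is selected if, in **every** training fold, it is the
most significant SNP of its LD block and reaches p ≤ 0.01 for **both**
traits. The score of sample *s* is then

    wGRS_s = Σ_i (risk-allele count of s at SNP i) × |slope_i|

with each SNP oriented to its ratio-increasing allele, and the score is
summarized by the mean wGRS per trait quartile with a linear trend fit.

## Worked example

```r
library(lipidgrs)

# A synthetic cohort with the published six-marker structure:
# 7016 samples, 6 causal SNPs + 54 null SNPs in LD blocks
sc  <- kare_like_scenario(seed = 7, n = 7016)
fit <- grs_fit(sc$genotypes, sc$phenotypes, seed = 7)
summary(fit)
```

```
Cross-validated weighted genetic risk score fit
  10-fold selection at alpha = 0.01: 6 SNP(s) selected
  weights (risk-allele oriented):
    tc_hdl_ratio: rs10852765=0.04301, rs12421652=0.1362, rs16940212=0.06833, rs17411126=0.1376, rs4420638=0.2125, rs6589566=0.1385
    log_tg_hdl_ratio: rs10852765=0.0007301, rs12421652=0.002461, rs16940212=0.0009413, rs17411126=0.002399, rs4420638=0.002483, rs6589566=0.002601
  quartile trends (score vs trait quartile):
    tc_hdl_ratio: means 0.602/0.65/0.692/0.74; slope 0.04552, p 1.24e-135, R2 0.9992
    log_tg_hdl_ratio: means 0.00989/0.0109/0.0117/0.0127; slope 0.000907, p 5.76e-209, R2 0.9954
  per-fold p-value range of selected SNPs:
    rs10852765: 1.44e-09 - 5.57e-05
    ...
```

The fit recovered exactly the six causal markers out of 60 candidates, with
risk-allele-oriented weights close to the simulated slopes (e.g. rs4420638:
0.2125 estimated vs 0.239 simulated for TC/HDL-c). Mean wGRS rises strictly
across trait quartiles with a near-perfect linear trend at the quartile-mean
level (R² > 0.99) and individual-level trend p-values far below 1e-4.
`coef(fit)` returns the weight matrix, `predict(fit, newdata)` scores a new
genotype panel with the training weights, and `plot(fit)` draws the
quartile-trend panels.

The staged command-line pipeline writes the same analysis to files with a
JSON run manifest per stage:

```sh
Rscript inst/cli/lipidgrs.R all --out run1 --seed 7
```

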