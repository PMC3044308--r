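# tfdensity

Predicting absolute gene expression in embryonic stem cells from the
genome-wide binding of core transcription factors (Oct4, Sox2, Nanog,
Klf4, ...) and the epigenetic state of promoters.

## The method

For gene *i* and factor *j*, the binding score sums the factor's ChIP-seq
peaks within ±50 kb of the gene's TSS,

    S_ij = Σ_k  g_k · F_j(l_k),

weighting each peak's intensity *g_k* by the factor's own **binding-density
profile** *F_j* — a max-normalized Gaussian kernel density (bandwidth
300 bp) of the factor's peak-to-nearest-TSS offsets — evaluated at the
peak's signed offset *l_k*. Unlike the classical exponential-decay weight
(TF association strength, `exp(-|l|/d0)`), the empirical profile can
represent factors that bind upstream-shifted, bimodal, or otherwise
non-monotone around the TSS. Log expression is then fitted by ordinary
least squares,

    log10(Y_i + 0.01) = a + Σ_j w_j S*_ij + α·H_i + β·M_i + γ·C_i + e_i,

with log-transformed, quantile-normalized scores S\* and ordinal codes for
histone state (none/H3K27me3/bivalent/H3K4me3 → 1–4), DNA methylation
(no annotation/methylated/unmethylated → 1–3) and CpG island
(absent/present → 1–2). Model quality is the mean held-out Pearson
correlation over 10 runs of 10-fold cross-validation (CV-R, CV-R²).

Around that core the package provides:

- a height-threshold peak caller on 200 bp extended tags with per-chromosome
  Monte-Carlo FDR and control fold-enrichment filtering (FDR < 5%, ≥ 5-fold);
- Kolmogorov–Smirnov comparison of binding profiles, including the test of
  absolute offsets against a fitted exponential distribution;
- AIC stepwise model reduction, and an exhaustive interaction search:
  all pairwise/triplewise products (469 terms for 14 variables) screened by
  sequential ANOVA F-tests, greedily assembled by cross-validated gain, and
  exported as a TF–epigenetics interaction network;
- ESC-specific (4-fold ESC/EB) and co-bound gene subsets, C1/C2 gene
  classification at 1 RPKM of predicted expression, and per-class epigenetic
  summaries;
- a fully synthetic study generator (genome, peaks with planted density
  profiles, tags with planted enriched loci, epigenetic states, expression
  with planted coefficients and interactions) so the whole pipeline runs
  and is tested without any external data.

## A worked example

```r
library(tfdensity)

sim <- simulate_study(n_genes = 500, seed = 1)   # synthetic study, planted R² = 0.6
fit <- expr_regression(sim$design, sim$y, seed = 1)
fit
#> Density-based expression regression
#>   n = 500 genes, 14 variables
#>   in-sample R2 = 0.6266, AIC = -5.08
#>   CV-R = 0.7764, CV-R2 = 0.6028 (10 x 10-fold)
```

The CV-R² of 0.60 matches the planted signal-to-noise (the generator
calibrates its Gaussian noise so the planted coefficients explain 60% of
the variance), and the fitted coefficients sit within a few standard
errors of the planted values:

```r
round(coef(fit)[c("Oct4", "Sox2", "HistM", "Methy", "CpGI")], 3)
#>  Oct4  Sox2 HistM Methy  CpGI
#> 0.535 0.479 0.265 0.194 0.228     # planted: 0.50 0.455 0.30 0.20 0.15
```

Classify genes by predicted expression and summarize epigenetic patterns:

```r
labels <- classify_c1_c2(predict(fit))           # "C1" (≥ 1 RPKM) / "C2"
epigenetic_summary(sim$genes$gene_id[labels == "C2"], sim$states)
```

Full workflows (`run_predict_workflow()`, `run_interaction_workflow()`)
orchestrate profiles → design → fit → classification and the per-TF-pair
interaction search from a single config list or YAML/JSON file, writing
profiles, fits, labels, networks and a digest-carrying run manifest. A thin
CLI lives at `inst/cli/tfdensity.R`.

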