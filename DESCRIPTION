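Package: tfdensity
Title: Density-Based Regression of Gene Expression on Transcription
    Factor Binding and Epigenetic State
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts absolute gene expression (RPKM) in embryonic stem
    cells from ChIP-seq binding data of core transcription factors and
    discrete promoter epigenetic states.  Peak-to-TSS offsets are
    summarised as max-normalized Gaussian kernel density profiles; each
    gene's score for a factor is the profile-weighted sum of peak
    intensities within +/-50 kb of its TSS, and log expression is fitted
    by multivariate linear regression with repeated 10-fold
    cross-validation, AIC stepwise reduction, and a greedy search over
    pairwise and triplewise interaction terms screened by sequential
    ANOVA.  Includes a height-based peak caller with Monte-Carlo FDR and
    control fold-enrichment filtering, ESC-specific and co-bound gene
    subset construction, C1/C2 gene classification by predicted
    expression, and a fully synthetic data generator with planted
    density profiles, coefficients and interaction effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
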