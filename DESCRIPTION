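Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and two-step MR
    mediation analysis from GWAS summary statistics. Implements instrument
    selection (genome-wide significance filtering, LD clumping,
    outcome-association exclusion, allele harmonization including palindromic
    resolution, weak-instrument F filtering), four pleiotropy-aware causal
    estimators (inverse-variance weighted, MR-Egger, weighted median, and
    MR-PRESSO with global, outlier and distortion tests), radial-MR outlier
    pruning, Cochran's Q heterogeneity statistics, and product-of-coefficients
    mediation with Aroian standard errors and mediated proportions. A
    summary-statistics simulator with configurable pleiotropy, planted
    outliers, LD blocks and palindromic variants supports validation, and a
    Tanimoto fingerprint screen ranks candidate molecules against reference
    drugs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
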