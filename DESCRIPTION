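Package: ratiomr
Title: Two-Sample Mendelian Randomization Screening with Protein-Ratio Mediators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-sample Mendelian randomization (MR) screening and mediation
    toolkit for GWAS summary statistics. Implements instrument selection
    (significance filtering, greedy linkage-disequilibrium clumping,
    F-statistic weak-instrument filtering), allele harmonization with
    palindromic-variant exclusion, inverse-variance-weighted and MR-Egger
    causal estimators with Cochran's Q heterogeneity and pleiotropy
    diagnostics, a simulation-based outlier test with removal and
    re-estimation (MR-PRESSO-style), Bayesian colocalization via Wakefield
    approximate Bayes factors (PPH0-PPH4), Benjamini-Hochberg false discovery
    rate correction, and two-step MR mediation with the mediated-proportion
    statistic. Ships a synthetic GWAS summary-statistics generator with a
    known exposure-mediator-outcome causal structure so every pipeline stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
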