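Package: targetmr
Title: Drug-Target Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample drug-target Mendelian randomization analysis built
    from GWAS summary statistics: cis-instrument selection around drug-target
    genes (genome-wide significance filtering and greedy LD clumping), allele
    harmonization with strand and palindrome handling, Steiger directionality
    filtering, instrument-strength F statistics, causal-effect estimation by
    inverse-variance weighting with MR-Egger, weighted-median, weighted-mode
    and maximum-likelihood sensitivity estimators, heterogeneity and
    pleiotropy diagnostics (Cochran Q, Egger intercept, leave-one-out),
    statistical power, Benjamini-Hochberg FDR across a target-by-outcome
    grid, fixed/random-effects meta-analysis, and a synthetic GWAS
    summary-statistics generator with known ground truth so that every stage
    of the pipeline is testable without external data downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    metafor,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
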