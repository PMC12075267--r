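Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample bidirectional Mendelian randomization from
    GWAS summary statistics: instrument selection (genome-wide significance
    filtering, greedy LD clumping, proxy lookup, F-statistics, confounder
    exclusion lists), allele harmonization with palindromic-SNP handling,
    causal-effect estimation by inverse-variance weighting, MR-Egger
    regression and the weighted median, heterogeneity and pleiotropy
    diagnostics (Cochran's Q, Rucker's Q', Egger intercept, leave-one-out,
    MR-PRESSO), summary-level and individual-level genetic risk scores,
    asymptotic power and sample-size calculation, and a seeded synthetic
    two-sample GWAS generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
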