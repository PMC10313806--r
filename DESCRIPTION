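Package: ptsdstrokemr
Title: Two-Sample Mendelian Randomization of PTSD Traits and Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization of
    genetic liability to post-traumatic stress disorder (PTSD) traits and
    ischemic stroke from GWAS summary statistics: instrument selection by
    p-value filtering and distance/LD clumping, effect-allele harmonization
    with palindromic-SNP handling, causal estimation by Wald ratio,
    inverse-variance weighting, MR-Egger and median estimators, heterogeneity
    and pleiotropy diagnostics (Cochran's Q and a PRESSO-style global test),
    and bidirectional orchestration. A synthetic GWAS summary-statistics
    generator with known causal structure makes every stage testable without
    consortium data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
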