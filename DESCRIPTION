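Package: twindiff
Title: Differential Expression Analysis for Discordant Monozygotic Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for discordant monozygotic twin gene
    expression studies: per-probe paired t statistics within each study,
    inverse-variance fixed-effect summarization of probe-level estimates to
    gene-level estimates, Benjamini-Hochberg false discovery rate control
    combined with a 95th-percentile absolute effect-size threshold, pairwise
    cross-phenotype comparison (significant-gene overlap and Spearman
    correlation of mean differences), per-gene DerSimonian-Laird
    random-effects meta-analysis across studies with heterogeneity statistics
    (tau-squared, Cochran Q, I-squared, QEp), and sex-stratified re-analysis.
    Includes a synthetic multi-study twin-cohort generator with known ground
    truth for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
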