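Package: snctrends
Title: Sliding-Window Age-Trend Analysis of Small Non-Coding RNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting progressive, age-correlated expression changes
    of small non-coding RNAs (microRNAs and snoRNAs) in cross-sectional
    leucocyte cohorts. Implements an age-ordered sliding-window correlation
    screen with z-scored window means and fold-change filtering, mean-trajectory
    crossing-age and acceleration-interval estimation, two-group (young vs
    elder) differential expression with an empirical-Bayes moderated t and
    Benjamini-Hochberg FDR control, screen comparison and candidate-selection
    cascades, hypergeometric gene-set overlap enrichment of miRNA targets, and
    delta-delta-Cq relative quantification for qPCR validation. Includes a
    synthetic-cohort generator with logistic age trajectories and ground-truth
    labels so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
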