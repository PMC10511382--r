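Package: tvarousal
Title: Visual Attention Parameters, Pupillary Unrest and Arousal Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of visual attention parameters
    (processing speed C, perceptual threshold t0, short-term memory capacity K,
    visual persistence mu and top-down control alpha) from whole- and
    partial-report letter paradigms under the theory of visual attention (TVA),
    computation of the pupillary unrest index (PUI, mm/min) and mean pupil
    diameter from raw 25-Hz pupillographic sleepiness test traces, and the
    statistical battery relating processing speed, central nervous activation
    and mental fatigue: rank-sum group tests with effect size r, bootstrapped
    kernel-density non-overlap, Spearman correlation matrices with
    Benjamini-Hochberg FDR control, bootstrap multiple regression with Cohen's
    f-squared, nested-model F tests and percentile-bootstrap mediation.
    Includes a synthetic-data generator for trial-level report data, pupil
    traces and whole cohorts with a target rank-correlation structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
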