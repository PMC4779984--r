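Package: qpcrdesign
Title: Variance Decomposition and Sampling-Plan Optimization for RT-qPCR
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies stage-wise technical noise in RT-qPCR workflows
    (sampling/RNA extraction, reverse transcription, qPCR) from nested
    pilot data using unbalanced nested random-effects ANOVA with
    method-of-moments estimation of variance components, and chooses the
    balanced replicate allocation that minimizes the expected variance of
    a group-mean Cq under a monetary budget. Includes a seeded
    hierarchical Gaussian simulator of Cq datasets, scalar noise calculus
    (total noise, replicate averaging, fold-change conversion, 3':5'
    integrity ratios), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
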