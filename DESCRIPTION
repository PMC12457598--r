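Package: boneagecal
Title: Population-Specific Calibration and Validation of Automated Bone
    Age Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for validating and linearly recalibrating automated
    (AI-based) bone age predictions against a multi-rater manual
    reference. Builds a bias-corrected, performance-weighted consensus
    bone age from a rater panel (with leave-one-rater-out benchmarking),
    fits sex-specific linear calibration models, computes agreement
    statistics (mean absolute difference, root mean squared error with
    chi-squared confidence intervals, signed mean difference with t-based
    intervals, one-year accuracy, intraclass correlation ICC(2,k),
    Bland-Altman limits of agreement, Lilliefors normality test), and
    quantifies the stability of the calibration under repeated
    age/sex-stratified train/test re-partitioning. A seeded synthetic
    cohort generator with known ground truth makes the full pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
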