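Package: lactshape
Title: Lactation Curve Modelling and Gestation-Length Cohort Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing first-lactation dairy records: per-lactation
    fitting of the four-parameter MilkBot curve by bounded multi-start
    nonlinear least squares, closed-form derived traits (305-day milk yield,
    time to peak, peak yield), gestation-length quantile categorization of a
    cohort, and multi-level mixed-model comparison of traits across
    gestation-length categories with least-squares means, pairwise contrasts
    and compact letter displays. Includes a synthetic herd-cohort generator
    with stored ground truth for parameter-recovery studies, and an
    end-to-end pipeline from raw milking and reproduction tables to a
    trait-by-category report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
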