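Package: grimkit
Title: Mouse Grimace Scale Criterion Importance and Severity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Mouse Grimace Scale (MGS) facial action unit
    scores from repeated-intervention studies. Ingests and aggregates per-image
    ordinal scores into per-video records, ranks the five facial action units
    by a coalition effect-size measure with exact Shapley attribution and,
    independently, by L1-penalized regression coefficients under the
    one-standard-error rule, fits random-intercept linear mixed-effects models
    of orbital tightening, discretizes scores into severity classes with
    chi-squared tests and pairwise post-hocs, and summarises score development
    with bootstrap median confidence intervals and Mann-Whitney contrasts.
    Includes a calibrated synthetic-data generator emulating a two-group
    (vehicle vs. hepatotoxic injection) four-week study design for end-to-end
    testing without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
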