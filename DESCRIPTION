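Package: pphscore
Title: Quality-of-Care Scoring and Determinant Analysis for Severe Postpartum Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a weighted, context-specific composite score for the
    quality of first-line management of severe postpartum hemorrhage (PPH)
    from per-woman care records, classifies "inadequate care" against an
    empirical percentile threshold, and analyses maternity-unit determinants
    of inadequate care with random-intercept logistic regression, multiple
    imputation by chained equations and Rubin's-rules pooling. Includes an
    eligibility filter with flow accounting, reporting tables, and a fully
    synthetic nested-cohort generator (women within maternity units) so the
    whole pipeline is exercisable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    nnet,
    MASS,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
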