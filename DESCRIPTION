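Package: rtmconformity
Title: Regression-toward-the-Mean Correction for Deviance-Based Conformity
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-session Likert rating experiments in the
    deviance-based social-conformity paradigm (an experimental group that sees
    an ostensible group judgment deviating by -2..+2 from its own rating, and
    a control group for which the same deviation is drawn but never shown) and
    implements a control-group based correction for regression toward the mean
    (RTM). A random-slope, fixed-zero-intercept hierarchical linear model is
    fitted to the control group by restricted maximum likelihood to estimate
    the average RTM slope of rating change on the mean-centered initial
    rating; that slope is then subtracted from every rating change to yield
    RTM-corrected per-item change estimates and per-participant Fisher-z
    conformity scores. Group-level inference uses mixed repeated-measures
    analysis of variance with Mauchly's sphericity test, Huynh-Feldt
    correction and generalized eta-squared, Holm-adjusted pairwise
    comparisons, and t tests with Cohen's d.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    car,
    optparse,
    withr
Config/testthat/edition: 3
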