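Package: ogttfda
Title: Functional Data Analysis of OGTT Glucose Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing oral glucose tolerance test (OGTT) glucose
    curves as functional data. Five timed glucose measurements per subject
    are smoothed into continuous curves by penalized B-spline least squares
    with a generalized cross-validation choice of the smoothing parameter.
    Functional principal component analysis extracts the dominant modes of
    between-subject variation and per-subject scores; functional analysis of
    variance compares group mean curves with permutation F tests, point-wise
    p-value curves and confidence bands. Traditional simple summary measures
    (fasting and 2-h values, trapezoid area under the curve, and a rule-based
    curve-shape index) are provided for comparison, together with multinomial
    logistic regression of a categorized later glycemic outcome on curve
    features, and a synthetic cohort generator that reproduces the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    nnet,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
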