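Package: drrisk
Title: Literature-Coefficient Logistic Risk Model for Diabetic Retinopathy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and exercises a Rothman-Keller style risk assessment
    model for diabetic retinopathy (DR) in type 2 diabetes: pooled odds
    ratios from published meta-analyses are converted to logistic
    regression coefficients, the intercept is anchored to the local DR
    prevalence, and individual patients are scored on the logit,
    probability and relative-risk (LP) scales. Includes a Monte Carlo
    simulation of the sorted probability curve used to place the
    high/low-risk dividing node, a synthetic two-group cohort generator
    whose per-factor odds ratios match a target evidence table, and
    from-scratch ROC/AUC, sensitivity and specificity machinery for
    validating scored cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
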