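Package: kidneylatent
Title: Latent Kidney Function from Routine Markers and 10-Year Cardiovascular Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a latent kidney-function trait from routine serum
    markers (creatinine, cystatin C, uric acid, blood urea nitrogen) via
    one-factor confirmatory factor analysis fitted by maximum likelihood,
    with five model variants that optionally adjust indicators for age and
    sex. Computes six standard estimated glomerular filtration rate (eGFR)
    equations (MDRD 4- and 6-variable, CKD-EPI 2009/2012/2021 families),
    10-year Framingham general cardiovascular risk and pooled cohort
    equation risk, and compares kidney indexes as predictors of
    dichotomized risk using C-statistics, DeLong tests and explained
    variance on log risk scores. Includes a seeded synthetic cohort
    generator with known generative truth so the whole pipeline is
    testable without individual-level cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
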