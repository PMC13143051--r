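Package: cremsex
Title: Probabilistic Sex Estimation for Human Cremated Remains from
    Postcranial Osteometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Missing-data-tolerant Gaussian naive-Bayes classification of
    skeletal sex from up to 21 postcranial measurements of calcined human
    remains, with univariate logistic-regression and cut-off baselines,
    sexual-dimorphism statistics (two-sample t tests and the
    Chakraborty-Majumder non-overlap index D), leave-one-out
    cross-validation with post-hoc probability filtering, reliability
    (calibration) curves, and rule-based warnings that flag possible
    commingling of more than one individual in a single deposit. Includes
    a reference model encoding published per-sex summary statistics from a
    Bronze/Iron-Age Italian training sample, a seeded synthetic-data
    generator emulating the heavy missingness of archaeological cremation
    burials, and a command-line interface for batch prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
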