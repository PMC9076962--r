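Package: ohcaudit
Title: Audit of Emergency-Call Handling for Out-of-Hospital Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to audit emergency medical dispatch centre handling of
    out-of-hospital cardiac arrest (OHCA) calls against the five American
    Heart Association performance goals for dispatcher-assisted CPR
    (DA-CPR). Implements the exclusion cascade used to construct the
    recognizable and DA-CPR-available cohorts, the goal metrics (recognition
    proportions, median times with threshold attainment) with benchmark
    verdicts, a counterfactual additional-survivors estimator, logistic
    regression of 30-day survival on restricted cubic splines of
    call-handling delay, and a seeded synthetic cohort generator so the
    whole pipeline is testable without registry access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
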