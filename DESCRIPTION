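Package: romtraj
Title: Recovery and Decline Trajectories of Shoulder Arthroplasty Range of Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Longitudinal trajectory analysis of active range of motion (ROM)
    after anatomic and reverse total shoulder arthroplasty. Computes per-visit
    rates of improvement over the two-year recovery period and rates of decline
    at long-term follow-up relative to the 2-3 year peak, classifies patients
    as fast, average, or slow by voting against prosthesis-specific cohort
    baselines, and screens patient, operative, and radiographic risk factors
    with univariate tests followed by multivariate logistic regression. A
    synthetic longitudinal cohort generator reproduces the recovery dynamics
    the analysis assumes (early post-surgical dip for high preoperative ROM,
    saturating recovery to a 2-3 year peak, late linear decline, covariate
    effects) so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
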