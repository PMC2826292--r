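Package: gripk
Title: Computerized Potassium Regulation for the ICU (GRIP-II Protocol)
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Advisory implementation of the nurse-centered GRIP-II computerized
    potassium regulation protocol for intensive care: renal assessment
    (Cockcroft-Gault clearance, clearance fraction), target-range
    classification, sliding-scale and within-range pump-rate recommendation,
    physician alerting and measurement scheduling. Includes a one-compartment
    virtual ICU patient simulator for closed-loop testing against a
    physician-emulator baseline, and an evaluation engine computing
    time-in-range prevalence from linearly interpolated potassium curves,
    dyskalemia incidence, odds ratios with Woolf confidence intervals,
    percentile time-course bands and before/after cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
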