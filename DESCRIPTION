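Package: relcal
Title: Individualized Accelerometer Cutpoints from Heart-Rate-Reserve Calibration
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibrates a per-subject linear relation between percent
    heart-rate reserve (%HRR) and accelerometer activity counts from a
    staged submaximal treadmill protocol, derives individualized
    counts-per-minute cutpoints at target relative intensities (40% and
    60% HRR by default), classifies minute-epoch count series under
    individualized or absolute (Freedson) cutpoint schemes, compares
    individualized cutpoints across cardiorespiratory-fitness groups, and
    simulates synthetic treadmill cohorts with fitness-dependent
    heart-rate response for end-to-end validation. Includes readers and
    writers for epoch-count and heart-rate CSV logs and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
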