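Package: secsurge
Title: Detection and Quantification of Nocturnal Blood Pressure Surges in
    Seconds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with overnight beat-by-beat systolic blood
    pressure recordings: a calibrated synthetic night generator with planted
    surge events, sliding-window detection of surge candidates (peak, start
    and 75%-decay end points), a 48-feature grouped description of each
    candidate, supervised acquisition of a physician-auditable AND-rule
    classifier via per-feature F-measure sweeps and exhaustive grid search,
    detection evaluation with night-level k-fold cross-validation, and
    conventional nocturnal blood pressure variables (mean, SD, CV, ARV)
    alongside per-surge severity variables with sleep-apnea attribution
    against polysomnography events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
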