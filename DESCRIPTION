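Package: playfall
Title: Head Injury Metrics and Surrogate Headform Drop Modelling for
    Playground Fall Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing head-first playground falls in children:
    zero-phase Butterworth filtering of impact kinematics, windowed Head
    Injury Criterion (HIC, HIC15, HIC36) maximisation, peak resultant
    kinematics, a reduced-order headform drop model of hysteretic rubber
    surfacing with critical fall height determination, tissue-level injury
    metrics (95th-percentile principal brain strain, peak skull stress),
    age-trend regression utilities for arguing age-dependent injury
    thresholds, and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
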