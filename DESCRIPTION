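Package: venotone
Title: Bedside Guytonian Venous Hemodynamics and Vasoactive Dose-Response
    from High-Frequency Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Guytonian venous parameters (mean circulatory filling
    pressure, venous resistance) and related hemodynamics (Fick cardiac index
    with a renal NIRS venous-saturation surrogate, indexed systemic vascular
    resistance, cerebral and renal oxygen extraction) from 1 Hz bedside
    monitoring data, and characterises vasoactive medication dose-response
    with per-outcome random-forest regression, feature importance, partial
    dependence and direction-of-effect calls. Includes a synthetic
    post-transplant cohort simulator with configurable monotone drug effects,
    slow postoperative trends, AR(1) noise and random missingness, plus
    venous-return / cardiac-function diagram construction with operating-point
    solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    ranger,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
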