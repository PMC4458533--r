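Package: accuprofile
Title: Accuracy-Profile (Total-Error) Validation of Bioanalytical Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validates quantitative bioanalytical methods with the
    total-error accuracy-profile approach: per-series linear calibration
    with inverse prediction (back-calculation), per-level trueness and
    precision from balanced one-way random-effects variance components,
    beta-expectation tolerance intervals with Satterthwaite degrees of
    freedom, the accuracy-profile decision rule with validated range and
    limits of quantification, and extraction-recovery statistics.
    Includes a synthetic plasma-assay data generator (day random effects,
    within-day error, linear response with internal-standard
    normalization, extraction recovery) and a Monte-Carlo harness for the
    coverage of the tolerance intervals, so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
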