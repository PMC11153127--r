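Package: opiometrics
Title: Kinematic Phenotyping, Fibre Photometry and Dose-Response Analysis for Opioid Withdrawal Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of markerless-pose tracking tables (coordinate
    correction, smoothing, arena calibration), extraction of per-frame
    kinematic variables, detection of withdrawal jumps and immobility bouts,
    place-preference scoring, two-channel fibre-photometry analysis
    (isosbestic regression, dF/F, transient detection by topographic
    prominence, trapezoidal AUC, peri-event averaging), feature-based
    time-series classification with cross-validated balanced accuracy and a
    label-shuffling permutation null, and four-parameter logistic
    dose-response fitting. Includes a fully seeded synthetic-data generator
    producing pose sessions, photometry recordings, dose-response tables and
    three-compartment occupancy tracks with ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    minpack.lm,
    pracma,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
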