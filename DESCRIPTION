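Package: appmarker
Title: Smartphone App-Usage Behavioral Markers for Depression Screening
Version: 0.1.0
Authors@R:
    person("Appmarker", "Developers", email = "appmarker@example.org",
           role = c("aut", "cre"))
Description: Transforms 7-day smartphone app-usage event logs into a grid of
    behavioral markers (diurnal durations and launch counts, unique-app
    counts, usage entropy, app-set Hamming-distance ratios, and gap-based
    usage sessions), screens participants with the PHQ-9, selects markers via
    four feature-selection regimes (information-gain filter, embedded
    random-forest ranking, Boruta-style all-relevant selection, and bootstrap
    stability selection), and classifies depressed vs. nondepressed
    participants under nested leave-one-participant-out cross-validation with
    a stacking ensemble. Ships a synthetic cohort generator with known group
    structure so that every pipeline stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    FNN,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
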