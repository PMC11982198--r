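Package: driftguard
Title: Population Drift Detection for Deployed Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a one-class support vector machine (nu-OCSVM with a
    radial basis function kernel) on a diagnostic training cohort and uses
    its decision frontier to monitor deployed clinical prediction models
    for population drift, without requiring ground-truth labels for new
    patients. Implements the full preparation chain (multicollinearity
    pruning by absolute Pearson correlation, SMOTE class balancing,
    z-score standardisation), a drifted-population simulator that offsets
    cohorts beyond the observed range of an anchor feature under Gaussian
    noise, tabular drift reports, and a windowed binomial alerting
    monitor for record streams. Includes a synthetic cohort generator
    emulating the Wisconsin Diagnostic Breast Cancer data structure so the
    whole pipeline is testable offline, and ships a plain-text copy of
    that public dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
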