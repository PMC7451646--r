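Package: stepsvm
Title: Stepwise Support Vector Machine Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward model selection for binary clinical outcomes driven by
    cross-validated support vector machine accuracy (StepSVM): all variable
    pairs are evaluated exhaustively, then variables are added one at a time
    while cross-validated accuracy strictly increases, up to a size cap.
    Includes the two standard comparators, linear-kernel SVM recursive
    feature elimination (SVM-RFE) and AIC-driven stepwise logistic
    regression scored by the concordance statistic, a synthetic generator
    for three-level hierarchical patient-within-doctor-within-hospital data
    with a binary remission outcome, and a replication harness producing
    selection-frequency tables and performance summaries across repeated
    simulations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
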