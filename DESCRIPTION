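Package: cofreezr
Title: Dyadic Co-Freezing Recurrence and Permutation Inference for
    Fear-Extinction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing social buffering of conditioned fear in rat
    dyads: freezing quantification from motion traces (>= 1 s immobility),
    conditioned-stimulus window scoring, time-lagged co-freezing recurrence
    profiles with a shuffled-partner null and per-lag paired-t/FDR group
    inference, permutation ANOVA and t tests, split-plot repeated-measures
    ANOVA, exact small-sample rank tests, ultrasonic-vocalisation band counts,
    open-field metrics, and a coupled two-state Markov simulator of dyadic
    freezing with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
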