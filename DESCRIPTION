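Package: dcreval
Title: Evaluation Toolkit for a Digital Clock-and-Recall Cognitive Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate a brief composite digital cognitive screen
    (clock drawing plus three-word delayed recall, scored 0-5 with
    Green/Yellow/Red bands) against the Mini-Mental State Examination.
    Provides a configurable synthetic-cohort simulator, norm-referenced
    rules-based cohort classification from RAVLT, TMT-B and FAQ scores,
    composite score computation, repeated stratified-split classifier
    evaluation with Youden-index thresholds and a paired permutation test
    on AUC distributions, threshold-based misclassification and rescue
    cross-tabulation, and a bootstrapped comparison of demographic bias
    between the two screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
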