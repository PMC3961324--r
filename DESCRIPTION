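Package: wpr
Title: Precision-Recall and ROC Curves for Weighted and Unweighted Test Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes precision-recall (PR) and receiver operating
    characteristic (ROC) curves, and the areas under them, for binary
    classifiers evaluated on test data with soft labels (per-point
    foreground and background weights) as well as ordinary hard-labeled
    data.  The area under the PR curve is obtained by exact piecewise
    integration of the hyperbolic precision function between adjacent
    supporting points, which extends AUC-PR to real-valued confusion
    matrices.  The classical discrete interpolations along true or false
    positives are provided for unweighted data, together with the
    attainable maximum and minimum AUC-PR for a given set of weights,
    normalized AUC-PR, Monte-Carlo random-classifier baselines, and
    simulation utilities for studying interpolation differences and the
    benefit of weight-aware evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
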