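Package: tacall
Title: Automated Amplification Calling for Arrayed qPCR Fluorescence Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the post-run analysis of arrayed quantitative PCR
    (TaqMan Array Card) amplification data. Raw reporter fluorescence is
    standardized against the ROX passive-reference dye and shift-normalized so
    every curve bottoms out at 1; the 40 per-cycle normalized values feed a
    two-stage gradient-boosted pipeline in which a classifier calls
    amplification and, conditionally on a positive call, a regressor predicts
    the cycle threshold (Ct). Calls with classifier probabilities between 0.1
    and 0.9 are flagged for manual review. Includes a seeded synthetic
    amplification-curve simulator with a closed-form ground-truth Ct,
    diagnostic-concordance evaluation (accuracy, Se, Sp, PPV, NPV, MAE with a
    Ct-40 convention for false positives), and multi-analyst comparison for
    external quality assessment exercises.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xgboost,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
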