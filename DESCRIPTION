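Package: sichscore
Title: SITS and OCSP-Extended Risk Scores for Post-Thrombolysis
    Symptomatic Intracerebral Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the 12-point SITS (Safe Implementation of
    Thrombolysis in Stroke) symptomatic intracerebral hemorrhage (SICH)
    risk score and a 15-point extension incorporating the Oxfordshire
    Community Stroke Project (OCSP) stroke-syndrome classification.
    Adjudicates SICH under the NINDS, ECASS II, and SITS-MOST
    definitions from structured follow-up data, and evaluates paired
    risk scores via univariate logistic regression, Hosmer-Lemeshow
    calibration, DeLong comparison of correlated ROC curves, bootstrap
    AUC confidence intervals, reclassification tables and categorical
    net reclassification improvement (NRI).  Includes a synthetic
    cohort generator so the full pipeline can be exercised end-to-end
    without patient-level registry data, plus command-line entry
    points for scoring, classification, adjudication, simulation and
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
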