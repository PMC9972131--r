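Package: scump
Title: Bot Detection in Likert-Type Questionnaires via Supervised Classes,
    Unsupervised Mixing Proportions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects fully random (bot) responders in Likert-type
    questionnaire data. Respondents are scored with nonresponsivity
    indices (Mahalanobis distance, person-total correlation, and optional
    factor-based coherence/reliability indices) relative to a human
    reference sample. Per-class Gaussian feature distributions are
    estimated from a stratified calibration sample; the target sample's
    contamination rate is then estimated by unsupervised maximum
    likelihood and respondents are classified with the Bayes rule, so the
    decision cutoff adapts to the contamination rate of the sample at
    hand. Also provides specificity-calibrated baseline classifiers, the
    closed-form two-normal specificity/accuracy theory, and a Monte Carlo
    simulation framework with a graded-response-model generator for
    synthetic human responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
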