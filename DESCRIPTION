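Package: painmeter
Title: Chronic-Pain Quantification from Multichannel Pulse and Temperature Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for quantifying chronic pain from low-cost
    physiological recordings: artifact-robust photoplethysmogram (PPG) peak
    detection and stability classification, height-invariant pulse-width and
    skin-temperature feature extraction over 10-second windows, per-subject
    linear models with recursive feature elimination and a pooled random-forest
    model, and a full evaluation harness (leave-one-recording-out
    cross-validation, Pearson r, RMSE, ICC(3,1), permutation null, and
    Bland-Altman agreement). Includes a synthetic cohort generator with a
    known, configurable pain-to-physiology coupling so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    ranger,
    stats,
    utils,
    tools
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
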