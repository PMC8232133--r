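Package: ccshock
Title: Shock-Advisory ECG Analysis During Chest Compressions with Fully
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and evaluating shock-advisory rhythm
    analysis of single-lead ECG recorded during cardiopulmonary
    resuscitation (CPR) chest compressions. Provides a synthetic
    compression-corrupted ECG (CC-ECG) simulator with SNR-controlled
    mixing of fibrillatory, organized and asystole rhythms with
    quasi-periodic compression artifacts; a parameterized fully
    convolutional network for 10 s strips with an exact shape and
    parameter-count calculus; trend-constrained random search over the
    architecture grid; the training protocol (Adam, binary cross-entropy,
    minority oversampling, early stopping); and an evaluation suite with
    sensitivity, specificity and balanced accuracy, ROC analysis,
    operating-threshold selection, and performance stratified by artifact
    SNR and compression rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
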