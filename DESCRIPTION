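Package: vtvfpredict
Title: ECG-Based Prediction of Imminent Malignant Ventricular Arrhythmia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for predicting imminent malignant
    ventricular arrhythmia (sustained ventricular tachycardia or
    fibrillation) from single-lead ECG. Reads WFDB-style or CSV records,
    removes outliers, partitions signals into one-minute segments, detects
    R-peaks with a Pan-Tompkins-style detector, delineates Q/S points and
    QRS onset/offset, extracts twelve time-domain heart-rate-variability
    and QRS-morphology features per segment, ranks features by
    decision-tree split-risk importance, selects an optimal subset by
    repeated 10-fold cross-validated error, and evaluates decision-tree,
    naive-Bayes and support-vector classifiers by sensitivity, specificity
    and prediction latency across 5-minute intervals before arrhythmia
    onset. A ground-truthed synthetic ECG generator makes every stage
    testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
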