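Package: eegfuse
Title: Microstate and Empirical Mode Decomposition Feature Fusion for EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-level fusion of EEG microstate dynamics and empirical
    mode decomposition (EMD) statistics for classifying schizophrenia and
    symptom severity from resting-state recordings. Implements global field
    power computation, polarity-invariant modified K-means microstate
    segmentation, the four microstate parameter families (mean duration,
    occurrence, coverage, transition probability), classic EMD sifting with
    per-IMF statistical features, IMF-averaged feature fusion, LASSO feature
    selection inside subject-wise stratified cross-validation folds,
    TPE-tuned (multinomial) logistic regression, and exact linear Shapley
    attributions. Includes a synthetic EEG cohort generator with known
    microstate ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    glmnet,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
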