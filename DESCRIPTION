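Package: ataximu
Title: Quantitative Assessment of Cerebellar Ataxia from Wearable IMU Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for objective severity assessment of
    cerebellar ataxia from inertial measurement unit (IMU) recordings of
    three bedside coordination tests: finger-to-nose (FNT), rapid
    alternating pronation-supination (DDK) and heel-to-shin (HST).
    Provides zero-phase Butterworth preprocessing, derivation of five
    kinematic measures per axis (linear acceleration and velocity, angular
    velocity, angular acceleration and angle), FFT resonant-frequency and
    resonant-magnitude features (60 per subject and test), univariate
    feature selection with Pearson correlation against clinical scores,
    PCA projection with silhouette separation, three-class linear
    discriminant severity scoring, and stratified k-fold cross-validation
    with ROC/AUC. A seeded synthetic-motion simulator emulates
    severity-dependent oscillatory limb movement so that every stage is
    testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    cluster,
    pROC,
    optparse
Config/testthat/edition: 3
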