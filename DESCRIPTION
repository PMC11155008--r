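Package: fedcrt
Title: Federated Learning Simulation for Predicting Chemoradiotherapy
    Response from CT Tumor Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multicenter federated learning (FedAvg) for
    predicting treatment response of non-small cell lung cancer from
    pre-treatment CT tumor patches, without any patient data. Provides a
    synthetic multi-site phantom cohort generator, CT-style preprocessing
    (isotropic B-spline resampling, tumor-centered 64-voxel patch
    extraction, 3D augmentation), a compact trainable 3D convolutional
    network, single-site training and synchronous federated averaging
    simulators, evaluation metrics (ROC/AUC with bootstrap confidence
    intervals, confusion-matrix rates), and the cohort-comparison
    statistics (chi-square, one-way ANOVA, Fisher's exact test) with the
    published multicenter cohort table shipped as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
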