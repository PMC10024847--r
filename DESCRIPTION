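Package: esotox
Title: Multi-Omics Prediction of Acute Radiation Esophagitis from Planning CT and 3D Dose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model grade >= 2 acute radiation esophagitis risk in
    thoracic radiotherapy from planning CT, 3D dose distributions, and the
    esophagus contour. Provides synthetic phantom cohorts, isotropic volume
    resampling with Hounsfield-window mask refinement, CT radiomics
    (first-order, grey-level co-occurrence and run-length texture, wavelet
    and Laplacian-of-Gaussian filtered variants), dosiomics (scale-invariant
    3D dose moments, dose-volume histogram Vx/Dx metrics, dose texture),
    bootstrap stability feature selection with correlation pruning,
    imbalance-aware easy-ensemble ridge classification over repeated
    stratified train-test splits, and nomogram export of the resulting
    linear risk score.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
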