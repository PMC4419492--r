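Package: rusmote
Title: Imbalance-Aware Lung Nodule ROI Classification with Combined
    Undersampling and SMOTE
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying lung-nodule regions of interest (ROIs)
    under severe class imbalance. Implements a combined balancer that removes
    boundary-noise samples from the majority class, undersamples the remainder
    by repeated halving, and oversamples the minority class with SMOTE linear
    interpolation; kernel soft-margin SVM training with optional per-class
    penalties (biased SVM); 2D/3D shape descriptors (circularity, elongation,
    compactness, moment, surface area, volume, sphericity, centroid offset)
    computed from binary voxel masks; imbalance-aware evaluation metrics
    (per-class accuracy, G-mean, F-measure); seeded synthetic generators for
    imbalanced feature clusters and toy nodule/non-nodule volumes; and a
    repeated stratified half-split cross-validation harness comparing plain,
    biased, SMOTE-balanced and combined-balanced SVM classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    EBImage,
    grDevices,
    RNifti,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
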