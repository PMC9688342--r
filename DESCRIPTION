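Package: lnlevelseg
Title: Patch-Based 3D UNet and Multi-View Voxel Classification for Neck
    Lymph Node Level Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments the elective cervical lymph node levels I-V on 3D
    CT volumes using three deep-learning configurations: a residual
    patch-based 3D UNet, a 2.5D multi-view multi-scale voxel classifier,
    and their sequential combination in which the UNet supplies a
    foreground mask that the multi-view network relabels into individual
    levels. Includes NIfTI input/output with isotropic resampling and CT
    intensity windowing, a synthetic neck phantom generator for
    end-to-end testing, truncated-Gaussian patch sampling with on-the-fly
    augmentation, weighted multi-class soft Dice and categorical
    cross-entropy losses with a compact convolutional network engine,
    cross-validated ensemble training, sliding-window center-crop
    inference with summed-probability ensemble fusion, morphological
    post-processing, and segmentation evaluation metrics (Dice,
    Hausdorff distance, mean surface distance, intraclass correlation,
    volume outside reference).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
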