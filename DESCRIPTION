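Package: podometrics
Title: Deep-Learning-Assisted Podocyte Morphometry, Stereology and Assay Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative podocyte phenotyping from
    histology micrographs: seeded synthetic scene generation with known ground
    truth, an encoder-decoder convolutional network for glomerular tuft and
    podocyte nucleus segmentation (with border weight maps and augmentation),
    per-glomerulus 2D morphometry with Otsu-based stain quantification,
    model-based stereological extrapolation to 3D (tuft volume, podocyte
    density and total count), filtration-slit density from STED-like z-stacks
    via skeletonization, plate-reader urine-chemistry calculations, a
    single-cell QC filter, and a pre-test screening decision tree for
    multi-group statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    nortest,
    car,
    stats,
    utils,
    grDevices,
    tiff,
    withr,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
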