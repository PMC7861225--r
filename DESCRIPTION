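Package: angioseg
Title: Patch-Based 3-D Convolutional Segmentation of Cerebral Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete patch-based framework for segmenting arterial
    vessels in 3-D time-of-flight angiography volumes. Implements a family
    of four 3-D encoder-decoder networks (a baseline U-Net, a dual-encoder
    multiscale context variant, a deeply supervised variant, and the full
    combination), together with the surrounding machinery: heuristic
    air-exclusion masking, vessel-centric two-scale patch sampling, a
    soft-Dice training loss with deep-supervision weighting, stratified
    k-fold cross-validation, whole-volume reconstruction from patch
    predictions, fold ensembling, and five-metric evaluation (precision,
    recall, Dice, average and 95th-percentile Hausdorff distance). The
    convolutional engine (3-D convolution, pooling, batch normalisation,
    backpropagation, Adam) is implemented natively on BLAS so the package
    has no deep-learning framework dependency. A synthetic vascular
    phantom generator makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
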