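Package: mvnn
Title: Multi-View Mammogram Classification with a Multi-Scale Attention DenseNet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage computer-aided screening and diagnosis of paired
    craniocaudal (CC) and mediolateral-oblique (MLO) mammograms. Implements a
    multi-scale attention DenseNet backbone (parallel channel/spatial attention
    with residual aggregation; hierarchical 4-way multi-scale convolution
    blocks with dense connectivity), a two-branch multi-view fusion classifier
    with a 1024-unit fusion layer, the accompanying preprocessing
    (CLAHE, bilateral filtering, normalization) and correlated two-view
    augmentation pipeline, SGD training with a frozen-convolution fine-tuning
    phase, stratified ten-fold evaluation (accuracy, sensitivity, ROC, AUC),
    gradient-weighted class-activation heat maps, and a synthetic two-view
    breast-phantom generator so the full pipeline runs without external data.
    All network layers, including backpropagation, are implemented natively
    (R with RcppArmadillo kernels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    utils,
    stats,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
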