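Package: DCAEC
Title: Deep Convolutional Autoencoder-Based Clustering of Single-Cell Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised clustering of label-free single-cell images from
    imaging flow cytometry with deep convolutional autoencoders (DCAE).
    Implements 2D, 3D and fused dual-modality autoencoders trained on
    mini-batch reconstruction error, encoder transfer into a Gaussian
    mixture clustering model with k-means initialization (DCAEC),
    cluster-to-class alignment and balanced-accuracy evaluation, and a
    Grad-CAM interpretability pipeline that discovers cluster-specific
    visual patterns and validates them by cross-validated classification
    of thresholded relevance masks. Includes a synthetic single-cell
    image generator so the full pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    pROC
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
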