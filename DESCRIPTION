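Package: picnet
Title: Proportional-Integral Feedback Stabilization for Convolutional Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feedback-control building blocks for small convolutional image
    classifiers: a discrete proportional-integral (PI) control law with an
    exact (non-decaying) integrator, a closed-loop image intensity
    preprocessor, fixed and learnable PI feature layers that fuse high-pass
    (proportional) and smoothing (integral) convolution paths at the input or
    mid-network, a PI-controlled gradient optimizer alongside SGD, momentum
    and Adam, compact CNN architectures with global-average-pooling heads,
    a seeded generator of CT-like nodule images with benign (smooth) versus
    malignant (spiculated) morphology, and an evaluation protocol with
    confusion-matrix metrics, Wilson score intervals, bootstrap resampling,
    Kruskal-Wallis and pairwise Wilcoxon tests, and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    pROC,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
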