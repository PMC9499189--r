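Package: lptbrain
Title: Rotation- and Scale-Invariant Brain MRI Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for classifying brain magnetic resonance images as
    normal or abnormal and tumors as benign or malignant when the input
    images may be rotated or rescaled. The pipeline combines log-polar
    resampling (which turns rotations into circular column shifts and
    uniform scalings into row shifts), a periodized orthogonal 2-D discrete
    wavelet transform, a 13-dimensional texture and intensity feature
    vector built from gray-level co-occurrence statistics and image
    moments, optional PCA/FastICA feature reduction, K-means segmentation
    of the lesion, and two classifiers: a kernel support vector machine
    (RBF, linear, polynomial, quadratic kernels) and a small
    four-convolutional-layer neural network trained with RMSprop. A
    built-in synthetic brain phantom generator with ground-truth lesion
    masks makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    grDevices,
    utils,
    png,
    jpeg,
    kernlab,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
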