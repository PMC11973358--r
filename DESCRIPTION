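Package: sparcnet
Title: Split-Convolution Attention Residual Networks for Histopathology
    Patch Classification
Version: 0.1.0
Authors@R:
    person("sparcnet", "developers", email = "sparcnet@example.org",
           role = c("aut", "cre"))
Description: Builds, profiles, trains and interprets a family of
    ResNet50-style convolutional classifiers for H&E-stained liver
    histopathology patches (cholangiocarcinoma, hepatocellular carcinoma,
    normal liver).  The family covers a plain bottleneck baseline, a
    split-based convolution variant that routes a representative channel
    fraction through grouped 3x3 filters and the redundant remainder
    through cheap 1x1 filters with parameter-free soft-attention fusion,
    a channel-plus-spatial attention (CBAM) variant, and the combined
    network.  Ships an analytic layer-by-layer parameter and FLOP
    profiler, a deterministic preprocessing pipeline (adaptive gamma
    correction, median filtering, bilinear resizing), seeded stochastic
    augmentation (elastic deformation, flips, random crop-and-resize), a
    full multi-class evaluation suite (confusion matrix, micro and macro
    precision/recall, F1, multiclass Matthews correlation, ROC and
    precision-recall curves), stratified k-fold cross-validation with
    early stopping, Grad-CAM saliency maps, and a seeded synthetic
    three-class H&E-like image generator so the whole pipeline is
    exercisable offline.  The neural-network engine (forward and reverse
    passes) is implemented in-package on dense linear algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: zlib
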