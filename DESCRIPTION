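Package: crstress
Title: Compression-Ratio Stress Testing for Deep-Learning Mammogram
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying how JPEG 2000 image
    compression affects convolutional-neural-network classification of
    mammographic studies.  Generates synthetic four-view mammogram-like
    studies with ground-truth lesion masks, compresses them to target
    compression ratios with rate control and PSNR accounting, applies the
    resize/crop/paired-view-concatenation preprocessing used for screening
    views, trains a small three-convolutional-layer binary classifier, and
    evaluates robustness with cross-validated AUROC/AUPRC over train-CR by
    test-CR matrices, mixed-CR augmentation experiments, and Grad-CAM
    saliency maps scored against the lesion masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    png,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
SystemRequirements: python3 with Pillow (OpenJPEG-enabled), numpy and
    tifffile on the PATH, used for JPEG 2000 encoding and decoding.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
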