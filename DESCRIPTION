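Package: uslesion
Title: Two-Stage Lesion Detection for Breast Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects hypoechoic tumour lesions in grayscale breast-ultrasound
    images with a two-stage pipeline: unsupervised region proposal (Canny
    edge detection followed by selective-search agglomeration), a
    confidence-gated region-of-interest classifier, iterative bounding-box
    regression with stepped intermediate targets, and Jaccard-clustering
    aggregation of the regressed boxes into a single detection. Ships a
    seeded speckle-phantom simulator (multiplicative gamma speckle,
    elliptical hypoechoic lesion, optional acoustic shadow, dark posterior
    band) so every stage is testable without clinical data, plus evaluation
    with IoU-based true/false positive counting and accuracy, precision,
    recall and F1.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
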