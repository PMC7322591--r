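Package: entropyDR
Title: Entropy-Image Preprocessing and a Bichannel Convolutional Network
    for Referable Diabetic Retinopathy Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening colour fundus photographs for referable
    diabetic retinopathy (grade 2 or worse). Implements green-component and
    luminance extraction, unsharp-mask enhancement, local Shannon-entropy
    image computation in sliding n-by-n windows, flip/rotation augmentation
    with class balancing and leakage-safe train/test splitting, a two-input
    ("bichannel") convolutional network trained with Adam on paired entropy
    images, and standard screening metrics (accuracy, sensitivity,
    specificity, ROC/AUC). A seeded synthetic fundus-phantom generator with
    grade-dependent lesion load makes the whole pipeline testable end to end
    without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
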