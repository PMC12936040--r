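Package: fenestra
Title: Detection and Measurement of Alveolar Bone Dehiscence and
    Fenestration on Sagittal CBCT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated localization, millimetre measurement and diagnosis of
    alveolar bone dehiscence and fenestration on 2D sagittal cone-beam CT
    slices. Provides a synthetic phantom generator for annotated slice
    triplets, a 12-channel mask/direction/heatmap supervision encoder, a 2D
    shifted-window transformer encoder-decoder network trained with a
    BCE+MSE composite loss on a built-in reverse-mode autodifferentiation
    engine, geometric endpoint decoding with threshold-based per-slice
    diagnosis and three-slice tooth-level consensus, and a full evaluation
    suite (keypoint localization, length agreement, Bland-Altman,
    classification and ROC statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
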