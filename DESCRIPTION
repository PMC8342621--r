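Package: pdl1tps
Title: Automated PD-L1 Tumor Proportion Scoring from H-DAB IHC Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline that converts PD-L1 (22C3) immunohistochemistry
    images into a tumor proportion score (TPS) and a three-level expression class:
    encoder-decoder tumor-region segmentation with a dilated residual encoder and
    atrous spatial pyramid pooling, unsupervised positive-membrane detection on the
    colour-deconvolved DAB plane (difference-of-Gaussians band-pass, luminance-adaptive
    multi-thresholding, luminance-weighted thresholding, morphological cleanup), and
    multi-resolution nuclei-centre detection trained on repel-coded proximity maps with
    non-maximum suppression. Includes the evaluation metrics used for such systems
    (overall pixel accuracy, point-detection F1 with one-to-one matching, MAE with
    bootstrap confidence intervals, Pearson correlation, three-class accuracy) and a
    synthetic H-DAB histology generator with complete ground truth so every stage is
    testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
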