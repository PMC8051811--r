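Package: nucann
Title: Automatic Annotation of Fluorescent Nuclei Images for Segmentation Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic generation of training-ready (image, instance mask)
    pairs from raw fluorescence microscopy images of stained cell nuclei.
    Implements a classical annotation pipeline: Otsu intensity thresholding by
    intra-class variance minimization, marker-based watershed instance
    labelling on the Euclidean distance transform, median-pixel-area object
    filtering to isolate the dominant single-nucleus class, and composition of
    filtered training images with additive background noise. Includes
    object-level evaluation (IoU-threshold matching, precision, recall, F1
    curves), a deterministic synthetic nuclei-field generator with exact
    ground truth for testing and benchmarking, and dataset import/export in
    label-map TIFF, per-instance mask folder, and CSV formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
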