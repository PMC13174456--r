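Package: dermatomics
Title: Automated Skin Histology Morphometry and Skin-Age Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated "imageomics" pipeline for quantifying intrinsic skin
    aging from histology. Segments the epidermis from H&E-stained skin section
    images via color filtering, optical-density stain deconvolution and
    morphological refinement; converts epidermal regions into skeleton graphs to
    locate the epidermal midline and validate rete ridges; extracts thickness and
    rete-ridge morphometrics; quantifies immunofluorescence markers (ITGB4 mean
    intensity, Ki67 proliferation indices, CD31 microvessel morphometrics); and
    trains Random Forest skin-age models (a full-feature model and a reduced
    top-8 model with degree-2 polynomial expansion) used to score longitudinal
    change such as xenograft rejuvenation deltas. A synthetic phantom generator
    provides ground-truth H&E-like slices, IF images and feature tables so the
    whole pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    randomForest,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    rlang,
    generics,
    withr,
    jsonlite,
    tiff,
    png,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
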