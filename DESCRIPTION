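Package: cardiotex
Title: Cardiac CT Radiomics Texture Analysis and Ensemble Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible radiomics pipeline for detecting left-ventricular
    remodeling from cardiac computed tomography. Provides mu +/- 3 sigma
    gray-level normalization of polygonal myocardial regions of interest,
    extraction of a 377-feature texture and geometry vector (histogram,
    gradient, gray-level co-occurrence, run-length, autoregressive model,
    Haar wavelet, and shape families), feature screening and autoscaling,
    an eleven-model classifier zoo, an ensemble machine-learning (EML)
    score with Youden cutoff and DeLong AUC, shadow-feature (Boruta-style)
    relevance selection, and group-comparison statistics with smile-plot
    coordinates. A synthetic two-class image cohort generator makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    jsonlite,
    mixOmics,
    nnet,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    xgboost
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
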