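Package: retmorph
Title: Retinal Vessel Morphometry and Cognitive-Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal microvascular parameters from artery/vein
    labelled vessel segmentation masks and models their association with
    cognitive impairment. Computes box-counting fractal dimension of the
    vessel centreline network, Knudtson-Hubbard central retinal arteriolar
    and venular equivalents (CRAE/CRVE) and their ratio (AVR) in the zone-B
    annulus around the optic disc, and global artery/vein width as vessel
    area divided by skeleton length. Includes a synthetic vascular-tree and
    fractal-fixture generator with known ground truth, a class-conditional
    cohort simulator, group comparisons and Pearson correlation screens,
    ROC analysis with Youden-index cut-offs, and a bagged random-forest
    classifier with Gini feature importances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    withr,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
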