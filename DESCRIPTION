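Package: pulmotex
Title: Texture-Based Lung CT Nodule Severity Classification with
    Bi-Level Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seedable re-implementation of a hybrid pipeline for
    grading lung CT nodules as normal, benign or malignant: Butterworth
    frequency-domain smoothing, grey-level co-occurrence (GLCM) texture
    features at four angles, bi-level feature selection combining a
    binary chaotic crow search wrapper with a Gini random forest
    (shadow-feature permutation importance, Wilcoxon screening and
    chi-square grouping), a sparse-coding super-resolution network with
    an unrolled ISTA layer, and a probabilistic neural network (PNN)
    Bayes classifier.  Includes a synthetic nodule phantom generator
    with known ground truth so every stage can be exercised and
    validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    randomForest,
    optparse
Config/testthat/edition: 3
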