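Package: genefold
Title: Genetic Folding Evolution of Support Vector Machine Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves custom support vector machine kernel functions with the
    Genetic Folding algorithm: linear chromosomes of operator/operand symbols
    carrying "left.right" folding indices are decoded into kernel expression
    trees, scored by cross-validated classification accuracy on a precomputed
    Gram matrix, and improved by tournament selection, one-point crossover
    with repair, category-preserving mutation and elitism.  Includes the
    surrounding binary-classification pipeline used for malignant/benign
    tumour feature tables: CSV feature-table input, min-max scaling, log
    transformation, Z-score outlier removal, stratified k-fold splitting,
    preset linear/polynomial/RBF kernels, a precomputed-kernel SVM bridge, a
    bagging ensemble, and accuracy/MSE/AUC/confusion metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    kernlab,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    e1071
Config/testthat/edition: 3
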