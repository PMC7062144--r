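Package: btrsign
Title: Sparse Binary/Ternary/Ratio Signature Models for Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns sparse, interpretable classification and regression models
    on microbiome abundance tables. Model coefficients are restricted to
    binary {0,1}, ternary {-1,0,1}, or numerator/denominator ratio structures
    (BTR models), so a fitted model reads as a balance between the cumulated
    abundances of two small groups of taxa. Models are searched with a genetic
    algorithm (an exhaustive enumerator is provided as an oracle for small
    problems), selected with a model-size penalty, and summarized as a family
    of statistically equivalent best models (FBM). The package includes
    permutation feature importance aggregated over the FBM, a leak-free
    repeated stratified cross-validation harness with elastic-net, random
    forest and linear SVM comparators, FBM co-occurrence analysis, and a
    synthetic compositional data generator with planted signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    randomForest,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
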