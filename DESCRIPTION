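Package: hetmda
Title: Heterogeneous-Network miRNA-Disease Association Prediction with
    Multi-Module Graph Attention and Support Vector Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a
    heterogeneous biological network. Integrates Gaussian interaction
    profile kernel similarity with miRNA functional similarity and
    DAG-based disease semantic similarity, derives meta-path adjacency
    matrices mediated by diseases, miRNAs and proteins, assembles three
    block-structured network modules, learns node embeddings with a
    two-level (neighbor and module) multi-head attention encoder
    pretrained by inner-product reconstruction of the association
    matrix, and classifies miRNA-disease pairs with an RBF-kernel
    support vector machine. Includes reliable-negative sampling by
    average-Euclidean-distance filtering, repeated stratified
    cross-validation with a full metric suite, parameter sweeps,
    case-study candidate ranking, and a synthetic network generator
    with planted low-rank structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
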