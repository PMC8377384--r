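Package: ppiboost
Title: Sequence-Based Protein-Protein Interaction Prediction with Gradient Tree Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for predicting protein-protein interactions from sequence
    alone. Proteins are encoded by four complementary descriptor families
    (pseudo amino acid composition, pseudo position-specific scoring matrix,
    reduced sequence and index-vectors, and Moreau-Broto/Moran/Geary
    autocorrelation), pair vectors are built by concatenation, redundant
    features are removed by L1-regularized logistic regression, and interaction
    labels are predicted by a stagewise gradient tree boosting classifier with
    binomial deviance loss. Includes readers for FASTA, labeled pair tables and
    PSI-BLAST ASCII position-specific scoring matrices, a synthetic-data
    generator with a plantable composition-similarity signal, stratified k-fold
    cross-validation with full binary-classification reports (recall,
    precision, accuracy, Matthews correlation, ROC and precision-recall
    curves), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
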