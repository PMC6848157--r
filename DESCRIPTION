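Package: promlex
Title: Promoter Identification and Strength Classification with Subword
    k-mer Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Two-layer classification of bacterial promoter sequences.
    DNA sequences are tokenized into sentences of overlapping k-mer
    "words" at n-gram levels 1-10, each level is embedded with
    subword-aware character n-gram vectors, the per-level sequence
    vectors are concatenated into a combined representation (1,000
    dimensions at defaults), optionally filtered by
    maximum-relevance-maximum-distance (MRMD) feature ranking, and
    classified with a small one-dimensional convolutional network
    (layer 1: promoter vs non-promoter; layer 2: strong vs weak
    promoter).  Includes a synthetic sigma70-style promoter generator
    with planted -35/-10 motifs, a stratified cross-validation harness
    with Chou-notation metrics, ROC/AUC, an exact one-sided Wilcoxon
    signed-rank comparison, and a k-nearest-neighbour baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
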