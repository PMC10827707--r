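Package: gmean
Title: Semi-Supervised GRU and K-Means Labelling of DNA Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-supervised classification of DNA sequences into two
    cell-line / transcription-factor-binding classes. Sequences are split
    into overlapping k-mers and tokenized against a corpus-derived
    vocabulary, a gated recurrent unit (GRU) network with a dense relu
    stack is trained on the labelled set, and unlabelled sequences are
    assigned to classes by 2-cluster K-means on the network's latent
    representation. Includes a synthetic motif-planted sequence generator,
    bidirectional and LSTM backbone variants, comparator predictors,
    per-class confusion-matrix metrics, and an end-to-end pipeline with a
    model-comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    randomForest,
    e1071,
    rpart,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
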