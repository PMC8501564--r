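Package: ordppi
Title: Ordinal Regression on Confidence Scores for Sequence-Based
    Protein-Protein Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions from primary sequence by
    modelling STRING-style confidence scores with an ordinal-regression
    decomposition. A pair of sequences is embedded per residue (one-hot,
    seven-class physicochemical, or skip-gram vectors), encoded by a siamese
    recurrent convolutional network (convolution, n-max pooling, bidirectional
    GRU with a concatenate or residual merge, global average pooling) whose two
    arms share parameters, fused by element-wise multiplication, and scored by
    K-1 binary sub-classifiers whose aggregated rank decodes to a confidence
    score; thresholding the score yields the interaction call. Ships AMSGrad
    training, a scalar-regression ablation head, a synthetic scored-pair
    generator with planted structure, evaluation utilities (confusion metrics,
    MAE/MSE, threshold sweeps) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
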