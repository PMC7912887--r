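Package: mirtarnet
Title: Hybrid Convolutional/Recurrent Prediction of miRNA Target Sites
Version: 0.1.0
Authors@R:
    person("mirtarnet", "developers", email = "mirtarnet@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a microRNA targets a candidate binding site
    from raw sequence alone, using a six-layer hybrid neural network
    (trainable nucleotide embedding, 1D convolution, max pooling,
    bidirectional LSTM and a two-layer dense head) trained end to end with
    backpropagation implemented natively in R. Includes the full
    data-encoding pipeline (orientation, padding, concatenation, integer
    encoding), a stratified split / grid-search / early-stopping training
    harness with repeated random re-splits, the seven standard evaluation
    metrics with percentile confidence intervals, a sliding-window scanner
    that calls target sites and target genes on long transcript sequences,
    a layer-removal ablation harness, and a synthetic miRNA:site dataset
    generator with planted seed-complementarity so every component can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
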