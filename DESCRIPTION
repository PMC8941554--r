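Package: EpochCPC
Title: Contrastive Predictive Coding for Physiological Signal Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-step self-supervised classification framework for
    fixed-length biomedical sensor epochs (EEG sleep stages, ECG beats).
    Step one trains a contrastive-predictive-coding pretext task on
    constructed positive/negative pairs of epochs: a dense encoder maps
    epochs to latents, a GRU summarises the left half of each pair into a
    context vector, and per-step linear predictors score the context
    against the right-half latents under a binary cross-entropy loss.
    Step two reuses the pretrained encoder in a lightweight supervised
    classifier (two distinct 1-D convolution layers and a softmax head)
    trained with a reduce-on-plateau learning-rate schedule. The package
    also provides a synthetic multi-class epoch generator, stratified
    splitting and label masking, confusion-matrix metrics (per-class
    precision/recall/F1, macro-F1, accuracy), a label-fraction experiment
    harness comparing pretrained against from-scratch training, epoch
    matrix file I/O, polyphase resampling, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
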