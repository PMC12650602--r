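Package: hctgnet
Title: Hybrid CNN-Transformer Heartbeat Classification with Gated Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for five-class (AAMI: N, S, V, F, Q) ECG
    heartbeat classification with a dual-branch neural network: a residual
    1-D convolutional branch for local beat morphology, a Transformer
    encoder branch with sinusoidal positional encoding for long-range
    temporal context, and a learnable per-dimension gated fusion of the two
    representations. Includes MIT-BIH-style WFDB record and annotation IO
    with AAMI symbol mapping, a preprocessing chain (zero-phase denoising,
    360 to 125 Hz Fourier resampling, 188-sample beat segmentation, z-score
    normalization), SMOTE class balancing for training data, a seeded
    training loop (Adam, cosine annealing, gradient clipping, early
    stopping), a confusion-matrix based evaluation suite, an ablation
    harness over model variants, and a synthetic annotated-ECG generator so
    the whole pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    caret,
    class,
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
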