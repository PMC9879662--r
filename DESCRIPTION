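Package: segfed
Title: Federated Medical Image Segmentation with Voting Ensembles, Genetic
    Hyperparameter Search, and a Hash-Chain Audit Ledger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a secured federated training workflow for binary
    medical-style image segmentation. Provides seeded generators for
    synthetic single-structure image/mask datasets; four small U-Net-family
    encoder-decoder networks (U-Net, nested-skip UNet++, full-scale-skip
    UNet 3+, and a fixed-cell NAS-style U-Net) with exact trainable-parameter
    accounting, deterministic initialisation, and stochastic-gradient
    training on binary cross-entropy; per-pixel plurality-vote fusion of
    model ensembles; a genetic algorithm over learning rate, epoch count and
    batch size with tournament selection, value or binary crossover, and
    mutation; intersection-over-union evaluation; and a SHA-512 hash-chain
    ledger with a site-authorization registry that records and audits every
    model update, detects tampered payloads and stale links, and supports an
    attack-detection experiment comparing audited and unaudited runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
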