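Package: scArch
Title: Multi-Scale Chromatin Architecture Calling from Single-Cell Hi-C
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls chromatin loops, TAD-like domains (TLDs) and A/B
    compartments from sparse single-cell Hi-C contact maps. Each
    chromosome of each cell is represented as a graph over 10 kb bins
    with sequence-derived (k-mer and CTCF motif) node features; a
    multi-task variational graph autoencoder with a GraphSAGE encoder
    and twin edge decoders is trained to reconstruct contacts and
    classify loops, and the per-bin latent embeddings feed
    connectivity-constrained hierarchical segmentation into TLDs (with
    CTCF boundary filtering and Wasserstein-based dynamic size
    selection), a two-state Gaussian hidden Markov model for
    GC-oriented compartment tracks, and downstream cell-identity
    feature encodings including tf-idf marker loop-anchor discovery.
    Consensus callers aggregate single-cell annotations across a
    population. A fully labelled synthetic single-cell Hi-C simulator
    (distance decay, planted loops, domains, compartments, and a
    synthetic genome with planted CTCF motifs and compartment-coupled
    GC content) supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Matrix,
    data.table,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    glmnet,
    optparse,
    withr,
    knitr,
    rmarkdown
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
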