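Package: capsRBP
Title: Capsule Network Modelling of circRNA-Binding Protein Sequence
    Specificities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the sequence specificities of RNA-binding proteins
    (RBPs) on circular RNAs from binding-site fragments. Fragments are
    one-hot encoded and classified by a capsule network: convolutional
    motif detectors with global max pooling feed primary capsules whose
    agreement with two digit capsules (bound / unbound) is computed by
    dynamic routing; training minimises a margin loss. Includes balanced
    dataset construction with exact dinucleotide-preserving shuffled
    negatives and boxplot length thresholding, stratified k-fold
    cross-validation with ROC/AUC evaluation, convolution-filter motif
    discovery with PFM/MEME export and sequence logos, wrap-aware sliding
    window scanning of full-length circular RNAs, and a planted-motif
    synthetic data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    withr,
    Biostrings,
    S4Vectors,
    IRanges
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
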