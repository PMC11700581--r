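Package: RNALocNet
Title: Subcellular Localization Prediction for lncRNAs and mRNAs with
    Long-Short Term Attention Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of RNA subcellular localization.
    Nucleotide sequences of arbitrary length are encoded per position with
    one-hot, electron-ion interaction pseudopotential (EIIP) and nucleotide
    chemical property (NCP) channels, aggregated by a stack of 1D
    convolutions with adaptive max pooling into a fixed-size feature map,
    and classified through a long-short term attention module fused with a
    bidirectional LSTM and a TextCNN head. Includes multi-class and
    multi-label focal losses for imbalanced compartments, stratified
    cross-validation with grid search, a full panel of evaluation metrics
    (accuracy, macro precision/recall/F1, MCC, micro/macro AUROC, micro
    AUPRC), a synthetic motif-planting dataset generator, and occlusion
    attribution for sequence-level interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
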