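Package: promcascade
Title: Cascaded Convolutional Classification of Bacterial Sigma-Factor Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies 81-nt bacterial DNA sequences as promoter or
    non-promoter and assigns promoters to one of six sigma-factor subclasses
    (sigma70, sigma54, sigma38, sigma32, sigma28, sigma24) using a cascade of
    six small binary convolutional neural networks trained on one-hot encoded
    sequence. Includes a synthetic promoter benchmark generator with planted
    -10/-35 hexamers, a greedy identity-based redundancy filter, stratified
    k-fold cross-validation, ROC/AUC and confusion-matrix metrics, a
    hyper-parameter grid, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
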