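Package: barcodekit
Title: Comparative Evaluation of DNA Barcode Species Identification
Version: 0.1.0
Authors@R:
    person("Barcodekit", "Developers", email = "barcodekit@example.org",
           role = c("aut", "cre"))
Description: A toolkit for comparative evaluation of DNA barcode markers
    and species-identification methods. Implements distance-based
    identification criteria (Best Match, Best Close Match, All Species
    Barcodes) with pairwise p, Jukes-Cantor (JC69) and Kimura
    two-parameter (K80) distances under pairwise deletion; automatic
    barcode-gap discovery with recursive single-linkage partitioning and
    group categorisation; alignment-based numeric encoding and
    alignment-free k-mer featurisation (spectrum, gappy and mismatch
    kernels); stratified k-fold cross-validation of supervised
    classifiers with accuracy, RMSE and per-species true-positive rates;
    corrected resampled paired t-tests for classifier comparison; and a
    seeded synthetic barcode-dataset generator with controlled intra- and
    interspecific divergence, singletons, indels and missing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
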