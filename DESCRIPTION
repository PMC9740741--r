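Package: accelgait
Title: Weight-Bearing Activity Recognition from Hip-Worn Triaxial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Signal processing and machine-learning pipeline for recognising
    standing, walking and jogging from raw hip-worn triaxial accelerometer
    recordings collected during incremental shuttle tests. Includes a
    synthetic cohort generator emulating the shuttle protocol, FIR high-pass
    preprocessing with overlapping 2-s windowing, eighteen per-axis features
    (statistical, spectral, Lempel-Ziv complexity, central tendency measure,
    correlation dimension and Daubechies-2 wavelet energies), nine feature-set
    constructions with PCA reduction and NCA feature selection, four
    classifiers (k-NN Manhattan/Euclidean, CART, linear SVM), and three
    validation protocols (70/30 split, 10-fold cross-validation,
    leave-one-source-out).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    rpart,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
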