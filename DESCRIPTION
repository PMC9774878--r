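Package: hsiseg
Title: Unsupervised Spatio-Spectral Segmentation of Biomedical
    Hyperspectral Images with Convolutional Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for unsupervised segmentation of Raman and infrared
    hyperspectral images (HSIs). An HSI cube is decomposed into
    overlapping patches, a convolutional autoencoder compresses each
    patch into a low-dimensional latent vector, and a Student's-t
    soft-assignment clustering head groups patches into tissue classes,
    optionally trained jointly with the autoencoder (end-to-end deep
    embedded clustering). Includes a synthetic tissue-phantom simulator
    (muscle with solid, striped and globular fat sections), a spectral
    k-means baseline, partition-agreement metrics (normalised mutual
    information, adjusted Rand score), label-map reconstruction from
    patch assignments, and readers/writers for ENVI and band-stacked
    TIFF cubes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
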