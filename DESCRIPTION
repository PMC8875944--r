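Package: fdcnet
Title: Fusion Convolutional Networks for Lung and Heart Sound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying digital auscultation recordings (lung
    sounds and phonocardiograms) from time-frequency feature images. Provides
    audio augmentation operators (background-noise mixing, pitch-preserving
    time stretching, duration-preserving pitch shifting), segmentation of
    recordings into 3-second windows, conversion of each window into 128x128
    spectrogram, MFCC and chromagram images, declarative builders for the
    FDC-1, FDC-2 and FDC-3 convolutional architectures and their late-fusion
    combination FDC-FS with exact shape inference and parameter accounting,
    a compact CPU training engine for those architectures, class-imbalance
    aware evaluation with support-weighted accuracy, and a synthetic
    auscultation-like data generator so the whole pipeline can be exercised
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
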