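Package: anuraclass
Title: Anuran Call Classification from Swept LPC and MFCC Spectral Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A bioacoustic species-classification pipeline for anuran
    (frog and toad) vocalizations. Builds coefficient-swept feature
    datasets from whole-call recordings using linear predictive coding
    (all-pole spectral envelopes via the Levinson-Durbin recursion) and
    mel-frequency cepstral coefficients (with a pre-emphasis sweep),
    reduces them with scatter-matrix principal component analysis, and
    classifies species with deep sigmoid networks and two-layer LSTM
    recurrent networks trained by the Adam optimizer. Includes a seeded
    synthetic call generator emulating a 35-species corpus, WAV input
    and output, stratified and group-aware train/test splitting, k-fold
    cross-validation, and a PCA-versus-no-PCA benchmark grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
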