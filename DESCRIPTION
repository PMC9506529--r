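Package: ftirnet
Title: FT-IR Spectral Pre-Processing and Two-Branch Neural Networks for
    Geographic-Origin Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric classification of attenuated-total-reflection
    FT-IR spectra by geographic origin. Implements six spectral
    pre-processing operators (min-max normalisation, Savitzky-Golay
    smoothing, mean centring, standard normal variate, multiplicative
    scatter correction, wavelet denoising) and the enumeration of their
    21 one- and two-step chains; PCA feature extraction for classical
    learners; a back-propagation network and a two-branch "Double-Net"
    classifier whose branch outputs are merged by elementwise
    summation; a stratified benchmark harness reporting test accuracy
    and macro-F1 per pre-processing configuration; and a synthetic
    ATR-FT-IR spectrum generator (Gaussian bands, class-dependent
    amplitude shifts, baseline drift, multiplicative scatter, additive
    noise) so the full pipeline runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    optparse,
    Rcpp,
    rpart,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
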