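Package: pdvoice
Title: Sustained-Vowel Voice Analysis for Parkinson's Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of sustained-vowel /a/ phonations for
    distinguishing Parkinson's disease voice from healthy-control voice.
    Provides a synthetic dysphonic-vowel generator with telephone and
    smartphone channel models, signal preprocessing (amplitude
    normalization, decimation, silence trimming, voiced-segment selection,
    fixed-duration clipping), a 23-entry phonation feature vector (F0 and
    formant statistics, five jitter and six shimmer variants,
    harmonics-to-noise ratio), windowed autoregressive spectral features
    (LPC, log-area-ratio, LPC-cepstral and mel-frequency cepstral
    coefficients via Levinson-Durbin recursion), linear- and mel-scale
    spectrogram matrices and images, and a repeated-holdout evaluation
    harness (random forest with Gini importance, forward stepwise-AIC
    logistic regression, a transfer-learning style convolutional-backbone
    classifier head, Monte-Carlo Shapley importance and rank-based AUC
    comparison tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    viridisLite,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jpeg
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'classify.R'
    'cnn.R'
    'dsp-utils.R'
    'evaluate.R'
    'formants.R'
    'pdvoice-package.R'
    'perturbation.R'
    'phonation.R'
    'pipeline.R'
    'pitch.R'
    'preprocess.R'
    'spectral.R'
    'spectrogram.R'
    'synthgen.R'
    'wav-io.R'
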