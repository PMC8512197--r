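Package: pcgscreen
Title: Phonocardiogram-Based Screening for Rheumatic Heart Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A segmentation-free pipeline for screening rheumatic heart
    disease (RHD) from single-channel heart-sound recordings. Recordings are
    bandpass filtered, resampled to 2 kHz, trimmed to a single 30-s segment
    and z-scored; each record is then summarised by 31 features spanning the
    time, frequency, perceptual (MFCC) and psychoacoustic (loudness,
    sharpness, roughness, fluctuation strength) domains and classified with a
    soft-margin RBF-kernel support vector machine. Generalisation to unseen
    subjects is estimated with two subject-level nested cross-validation
    protocols: stratified 10-fold, and a prevalence-controlled imbalanced
    protocol for screening settings where cases are rare. A synthetic
    phonocardiogram simulator with configurable murmurs and noise makes the
    whole pipeline runnable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
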