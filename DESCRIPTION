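Package: alphacouple
Title: Source-Localized EEG Alpha Power Coupling with Simultaneous fMRI
Version: 0.1.0
Authors@R: person("alphacouple", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for source-localization-driven integration of
    simultaneously recorded EEG and fMRI. Cleans in-scanner EEG (MR gradient
    and ballistocardiogram template subtraction, amplitude rejection, ICA,
    average reference with spherical-spline pseudo-electrodes), computes
    induced alpha power by Morlet wavelet and short-time FFT, estimates
    cortical sources with a four-shell spherical head model and a weighted
    minimum-norm inverse with noise normalization, extracts single-trial
    patch-of-interest alpha values, and regresses their HRF-convolved time
    course against BOLD volumes with Monte-Carlo cluster thresholding. A
    synthetic multimodal session generator provides ground truth for every
    stage, so the whole chain is verifiable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
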