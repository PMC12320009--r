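Package: opmpipe
Title: Analysis Pipelines for Wearable OPM-MEG Evoked and Frequency-Tagged Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel optically pumped magnetometer (OPM)
    magnetoencephalography recordings of auditory evoked and frequency-tagged
    oddball responses, aimed at infant-sized sensor arrays. Provides a synthetic
    recording generator with known ground truth (spherical-conductor dipole
    physics, heartbeat and movement artifacts, 1/f noise), a preprocessing chain
    (artifact interpolation, zero-phase filtering, robust z-score rejection,
    principal-component projection, ICA-based heartbeat removal), evoked-response
    epoching and metrics, the flanking-bin power-spectrum SNR statistic for
    steady-state responses, step-down maximum-statistics inference with sign-flip
    and Fourier phase-randomization surrogates, and a noise-normalized
    minimum-norm inverse on a spherical head model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
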