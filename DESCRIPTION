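Package: soundelev
Title: Bayesian Spectral-Cue Models of Sound-Source Elevation Localisation and Perceptual Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates human sound-source elevation estimation in the median
    plane as a Bayesian ideal observer: a spectrally weighted sensory spectrum
    is cross-correlated with stored head-related transfer function (HRTF)
    templates, the rectified correlation serves as a likelihood that is
    combined with a Gaussian spatial prior, and the maximum a-posteriori (MAP)
    elevation is reported. Includes a synthetic HRTF generator with the
    canonical cue structure (ear-canal resonance, elevation-dependent spectral
    notch, weak low-frequency cues, erratic high-frequency cues), the standard
    spectrally degraded stimuli (band-stop and low-pass noises), trial-level
    simulators for perceptual-learning experiments with and without visual
    feedback, spectral-weight update rules, and the accompanying psychophysics
    toolkit (stimulus-response regression, windowed regression, mean absolute
    errors, exact one-sided sign tests, double-pole target sampling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
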