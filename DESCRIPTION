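Package: audmark
Title: Neural and Behavioral Markers of Multi-Talker Speech Intelligibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Signal-processing and psychophysics pipeline for studying why
    listeners with clinically normal audiograms differ in multi-talker speech
    intelligibility. Synthesizes the acoustic stimuli (frequency-modulated
    tones, interaural phase difference trains, tone pips), extracts
    frequency-following responses from alternating-polarity EEG epochs by
    heterodyne phase demodulation with bootstrap averaging, measures interaural
    phase difference following responses and envelope following responses by
    spectral projection, picks auditory brainstem response wave-1 amplitudes,
    runs transformed up-down adaptive staircases and a multi-talker digits
    protocol with maximum-likelihood threshold estimation, preprocesses
    pupillometry traces into an index of listening effort, fits sigmoidal
    growth functions with a min-max/half-max slope metric, and links the
    markers to speech reception thresholds through univariate correlations and
    a forward multivariable regression with adjusted R-squared. A synthetic
    data module generates every input with known ground truth so the whole
    chain is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
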