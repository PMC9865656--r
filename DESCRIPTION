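Package: breathradar
Title: Few-Shot Adaptable Respiration Sensing from FMCW Radar Phase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-contact respiration-signal estimation from 60 GHz
    frequency-modulated continuous-wave (FMCW) radar recordings. Implements
    the full processing chain: a synthetic FMCW breathing-scene simulator
    (chest displacement, static clutter, motion bursts, quantized reference
    belt), range-FFT preprocessing with dynamic range-bin tracking and moving
    target indication clutter removal, phase unwrapping, cascaded biquad
    band-pass respiration filtering, autocorrelation-based motion-corruption
    detection, a central-frequency-constrained convolutional variational
    autoencoder mapping radar phase to a reference belt signal, episodic
    meta-learning (first- and second-order MAML, Reptile, and a stabilized
    MAML variant) for few-shot adaptation to new users, and a
    corruption-weighted fusion estimator of the breathing waveform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
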