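Package: thetawake
Title: Local Sleep-Like Theta Events and Sleep-Pressure Markers in Wake EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and statistical analysis of local sleep-like events in
    multichannel wake EEG: area-averaged theta-band (5-7 Hz) reference signals,
    robust median-deviation thresholding, negative-peak detection between theta
    maxima, lagged cross-correlation globality with isolated-channel pruning,
    and trough-to-peak amplitude at the median-slope channel. Also provides
    phase-rectified signal averaging (PRSA), Welch power spectra with
    scalp-average normalised band topographies, sensor-space permutation
    cluster statistics for paired topographic contrasts, reaction-time
    linkage of events to behaviour, and a synthetic EEG generator with ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
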