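Package: fnirseeg
Title: Simulation and Analysis of Co-Located EEG-fNIRS Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing co-located electroencephalography
    (EEG) and functional near-infrared spectroscopy (fNIRS) recordings such as
    those produced by wearable prefrontal sensor patches. Provides a synthetic
    dual-modal acquisition simulator (Stroop-style event schedules, canonical
    double-gamma haemodynamic responses with physiological noise and motion
    artifacts, forward modified Beer-Lambert optics, event-related potential
    templates embedded in 1/f EEG background, and LED time-division-multiplexing
    crosstalk), the modified Beer-Lambert inversion to oxy-/deoxy-haemoglobin
    concentration changes, an fNIRS cleaning chain (polynomial detrending,
    temporal derivative distribution repair, zero-phase Butterworth band-pass
    implemented in numerically stable second-order sections), ERP epoching and
    component extraction, acquisition-quality metrics (input-referred noise,
    amplitude and frequency distortion, crosstalk residual), and the
    electrophysiology-haemodynamics coupling statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
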