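Package: tiskit
Title: Carrier-Frequency Biophysics of Temporal Interference Nerve Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing kilohertz-carrier transcutaneous nerve
    stimulation, including temporal interference stimulation (TIS).
    Synthesizes TIS, amplitude-modulated, burst and plain sinusoidal
    stimulation waveforms and their envelopes; evaluates and fits the
    Reilly strength-frequency threshold equation; simulates a simplified
    myelinated-axon cable model that exhibits kHz rectification, temporal
    summation and beat-locked firing; computes the closed-form
    time-over-threshold statistic for interfering activating-function
    amplitudes; solves a layered anisotropic quasi-static volume
    conductor with constant-phase-element electrode-skin interfaces;
    and generates synthetic threshold-study datasets with the ramp
    quantization and effect structure of locust and human experiments.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
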