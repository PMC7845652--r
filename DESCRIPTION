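Package: nmeserd
Title: Sensorimotor EEG Oscillatory Analysis Under Neuromuscular
    Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of multichannel EEG recorded during
    neuromuscular electrical stimulation (NMES). Provides a synthetic
    session generator with known ground-truth alpha/beta event-related
    desynchronization (ERD), 35 Hz pulse-train artifacts and bad-impedance
    channels; a two-step artifact removal procedure (iterative
    power-line-based channel rejection and a sliding median filter with a
    frequency-attenuation profiler); preprocessing (common average
    reference, band-pass filtering, stimulation-onset alignment, epoching,
    downsampling, pooling by intensity); Morlet wavelet time-frequency
    ERD/ERS quantification with band, interval and region-of-interest
    summaries; and trial-wise dose-effect linear regressions with Pearson
    correlation. Sessions round-trip through EDF+ files with annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    yaml,
    jsonlite,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
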