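Package: ansindex
Title: Autonomic Nervous System Indices from Electrodermal Activity and
    Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes time-domain and spectral indices of sympathetic and
    parasympathetic activity from raw physiological recordings: skin
    conductance level (SCL) and non-specific skin conductance responses
    (NSSCRs) from tonic/phasic decomposition of electrodermal activity
    (EDA), spectral sympathetic indices (EDASymp, and the time-varying
    TVSymp via variable frequency complex demodulation), and spectral
    heart rate variability (HRV) indices from envelope-based R-peak
    detection and cubic-spline RR resampling.  Includes go/no-go
    (error awareness task) performance metrics, Friedman rank analysis
    across repeated runs with rank-based post-hoc comparisons, and a
    fully deterministic synthetic-data generator (Bateman-kernel SCR
    trains, template ECG with LF/HF rate modulation, trial logs with
    learning and fatigue profiles) that exposes ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
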