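Package: caninehrv
Title: Sleep-Window Heart Rate Variability Analysis for Canine Holter Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for heart rate variability (HRV) analysis of nocturnal
    (sleep-window) Holter beat annotations in dogs: reading beat/RR records,
    wall-clock window selection, NN-interval filtering, linear indices (SDNN,
    RMSSD, spectral band powers TP/ULF/VLF/LF/HF with normalized HF and LF/HF),
    nonlinear indices (Poincare SD1/SD2 ellipse descriptors, phase-rectified
    signal averaging acceleration and deceleration capacity), and paired
    pre/post comparison with the exact Wilcoxon signed-rank test. Includes an
    integral pulse frequency modulation (IPFM) simulator of canine RR series
    with respiratory sinus arrhythmia, low-frequency modulation, optional
    ectopic/missed-beat contamination, and a tunable sympathovagal shift, so
    the full pipeline can be exercised and calibrated without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
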