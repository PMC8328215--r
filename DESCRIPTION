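Package: segphase
Title: Delta-Band Phase and Downstream ERP Amplitude Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether the phase of slow (delta-band, < 4 Hz)
    EEG oscillations at a sentence-internal segmentation point predicts the
    single-trial amplitude of a downstream P600-like event-related potential.
    Provides a synthetic phase-coupled EEG generator with known ground truth,
    deterministic signal conditioning (zero-phase Butterworth filtering,
    resampling, epoching, baseline correction, average re-referencing),
    spatio-temporal cluster-based permutation statistics for ERP contrasts,
    circular-linear phase-amplitude correlation with a trial-shuffled
    surrogate null and Benjamini-Hochberg FDR control, preferred-phase
    estimation, and a coherence-based prosody control, orchestrated as a
    reproducible seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
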