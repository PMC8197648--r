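Package: tacsphase
Title: Phase-Dependent Modulation of Speech Comprehension by
    Envelope-Based Transcranial Alternating Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how transcranial alternating current
    stimulation (tACS) with speech-envelope-derived waveforms modulates
    speech-in-noise comprehension. Generates theta-band stimulation
    currents from audio (envelope extraction, zero-phase bandpass,
    extrema equalization, analytic-signal phase shifts, sham pulses),
    fits harmonic (sine/cosine) regression models of comprehension
    versus stimulation phase with ordinary and robust (IRLS) estimation,
    FDR correction and bootstrap model comparison, analyses per-subject
    best phases with circular statistics (Rayleigh test, von Mises fits,
    Watson goodness of fit, concentration homogeneity), simulates the
    adaptive 1-up/1-down sentence-reception-threshold staircase, and
    generates synthetic cohorts and surrogate envelope pairs for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    sandwich,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
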