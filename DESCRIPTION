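Package: assrload
Title: Auditory Steady-State Response Analysis Under Visual Perceptual Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for 40-Hz auditory steady-state
    responses (ASSRs) recorded while observers perform a visual detection task
    under varying perceptual load. Generates multi-channel synthetic EEG with
    known ground truth (amplitude-modulated tone response, 1/f background,
    blinks, visual event-related potentials, behavioural responses, complex-span
    working-memory sessions), preprocesses it (zero-phase Butterworth high-pass,
    nose re-referencing, epoching, range-based artifact rejection), and derives
    the study measures: signal-minus-noise (SmN) spectral amplitude and
    intertrial phase coherence (ITC) at the modulation frequency, a nested 2-Hz
    analysis of the 40-Hz envelope, the visual P3 manipulation check, d-prime
    and reaction times, and partial-credit-unit working-memory scores. Group
    inference uses Bayes factors with uniform, Cauchy (JZS), and flat
    correlation priors, plus repeated-measures ANOVA with linear-trend
    contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
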