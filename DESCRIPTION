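Package: swdquant
Title: Quantification of Hyperventilation-Provoked Spike-Wave Seizures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-analysis pipeline for quantifying spike-wave seizures
    (SWS/SWD) in chronically instrumented rats challenged with hypoxia,
    hypercapnia, or optogenetic stimulation of brainstem respiratory
    centers. Refines manually annotated seizure windows to first/last
    supra-threshold peak boundaries (2.5 x pre-event RMS), characterizes
    events by dominant frequency and 5-8 Hz harmonic content, estimates
    respiratory rate from whole-body plethysmography via windowed FFT,
    builds peristimulus time histograms around gas-exchange or laser
    onsets, and applies normality-gated paired statistics and
    sphericity-corrected repeated-measures ANOVA. Includes a synthetic
    session generator (harmonic SWD bursts in 1/f ECoG background, EMG
    atonia, condition-dependent breathing, exponential chamber-gas
    exchange, 20 Hz laser pulse trains) so every stage is testable
    against ground truth without animal data.
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
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
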