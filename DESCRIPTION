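Package: synfire
Title: Spike-Train, Burst and Pharmacology Analysis for Dopamine Neuron
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for current-clamp recordings of spontaneously
    firing dopamine neurons: derivative-threshold spike detection with
    per-spike waveform features and phase-plane portraits, Grace-Bunney
    interspike-interval burst classification with percent-spikes-within-burst
    and up-state (depolarized plateau) quantification, interspike-interval
    distribution and coefficient-of-variation summaries, baseline-versus-drug
    epoch comparison, binned time courses of agonist-evoked currents with
    Kolmogorov-Smirnov comparison, and delta-F-over-F0 quantification of
    fluorescent dopamine-sensor recordings.  A phenomenological
    membrane-potential simulator plants exact spike, burst and plateau ground
    truth so every analysis stage can be validated against a known answer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
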