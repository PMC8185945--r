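---
title: "Quantifying dopamine-neuron firing patterns: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dopamine-neuron firing patterns: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synfire)
```

This vignette documents the models and estimators behind the package's
operations, the tunable parameters and why their defaults are what they are,
what the synthetic generator does and does not emulate, and the numerical
choices that were genuinely open. Everything empirical stated here is
computed by the package's own tests or by `scripts/acceptance.R`; the
vignette itself makes no claims the code does not check.

## Units and conventions

Time is in seconds internally, everywhere. Milliseconds appear only in
user-facing parameters that the field quotes in ms (refractory period,
half-width, blanking window); they are converted once at the interface. A
single internal convention prevents the classic 80 ms / 0.08 s threshold
bug. Voltages are mV, currents pA, derivatives V/s.

Traces must be uniformly sampled: any sample interval deviating more than 1%
from the median is rejected at construction, because the central-difference
derivative that anchors spike detection assumes a constant step. Recordings
are assumed to be 10 kHz when a synthetic fixture needs a concrete rate;
that choice is an assumption, not a measurement.

## Spike detection and waveform features

Detection is a derivative-threshold operator: an upward crossing of
`dvdt_threshold` (default 10 V/s) opens a candidate; the spike is anchored
at the voltage argmax within a short lookahead (default 5 ms) after the
crossing; candidates below `min_peak` (default −10 mV absolute) are
discarded; peaks closer than the refractory period (default 2 ms) merge,
keeping the higher. The argmax-in-window form matters under noise: a plain
"next local maximum" can anchor on a noise blip on the upstroke, below
`min_peak`, and silently drop the real spike.

The action-potential *threshold voltage* is defined as the voltage at the
last upward crossing of the dV/dt criterion before the peak. This choice is
what makes "amplitude" (peak − threshold) and "half-maximal voltage"
well-defined quantities; analysis software conventions differ and the
quantity is rarely spelled out in papers. Half-width is then the time
between the two crossings of threshold + amplitude/2, linearly interpolated
between samples — the common electrophysiology convention. Spikes whose
measurement window is clipped by a trace edge are flagged and excluded from
summaries rather than silently truncated.

Two closed forms pin the implementation down: a Gaussian bump of standard
deviation σ measured from its baseline must return a half-width of
2σ√(2 ln 2), and the phase-plane portrait of A·sin(2πft) must reach a
maximal |dV/dt| of 2πfA. Both are asserted in the tests at one-sample and
0.5% tolerances respectively.

Inclusion criteria follow the standard current-clamp rule: resting membrane
potential below −35 mV and mean spike amplitude (peak to resting) above
60 mV. The resting potential is estimated as the histogram mode (0.5 mV
bins) of the spike-blanked voltage rather than its mean: in bursting traces
the mean is dragged upward by depolarized plateaus, while the mode tracks
the down-state.

## Burst classification and the up-state

Bursts use the Grace–Bunney interspike-interval rule with the parameter
values standard for dopamine neurons: a burst opens at the first spike pair
with ISI strictly below 80 ms, spikes join while ISIs stay at or below
160 ms, and the first ISI strictly above 160 ms closes it. The strictness at
both boundaries is a deliberate, tested reading; boundary trains such as
ISIs of exactly 80 or 160 ms exercise it in the tests, and the whole rule is
verified against an independently written state machine on 1,000 random
trains. A burst still open at the final spike is closed there and flagged
`truncated` rather than dropped — the information is preserved without
biasing duration statistics. The minimum burst size is 2, because the onset
pair itself constitutes a burst under the quoted rule; requiring 3 is a
plausible alternative that the parameters expose.

%SWB is the count of spikes inside any burst over the neuron's total spike
count, ×100.

The *up-state* is reported as a difference: the published group values of a
few to ~14 mV are far from any absolute membrane potential, so the quantity
must be the depolarization of the in-burst potential relative to the
down-state. How that level was estimated is not specified in the source
material, so the estimator here is explicit: spikes are blanked ±5 ms with a
linear bridge, the up-state level is the *median* of the blanked voltage
inside burst intervals, the down-state level the median outside, and the
up-state value is their difference. The median (rather than mean) is robust
to residual spike shoulders that survive blanking; recovery of planted
plateaus of 5.91, 10.54 and 14.13 mV within ±0.5 mV under 0.5 mV noise is
part of the acceptance checks.

## ISI distributions, CV, and epochs

ISI distributions and their cumulative-probability curves are strictly
per-neuron; group aggregation happens only on scalar summaries. The CV of
the ISI is SD/mean × 100% with the *sample* SD (n−1) — the n-convention is
untestable from published values, so the choice is made explicit and
asserted. (The published group CVs of ~2.7 and ~5.1 are internally
inconsistent with a percentage definition; this package computes the defined
percentage and leaves the interpretation of printed values to the reader.)
The default analysis window is the first 60 s of stable recording,
configurable.

Epoch comparison runs the identical analysis chain on a baseline window (by
default the 60 s ending at drug onset) and a drug window (by default 60 s
starting 7 min after onset, the conventional wash-in delay; configurable to
7–10 min). Swapping the two windows provably swaps the metric columns. For
the synthetic regime-switch scenarios the analysis uses 120-s windows with a
20-s post-switch delay: the planted switch is instantaneous, so no wash-in
has to be waited out, and the longer windows keep at least one burst/pause
cycle in every window given the long planted pauses (truncated-normal,
mean 40 s, up to 80 s).

Evoked-current and fluorescence time courses are compared on 1-s bin means
(trailing partial bins dropped) with a two-sample Kolmogorov–Smirnov test,
asymptotic p. Whether such comparisons should use binned means or raw
samples is ambiguous in common practice; binned is the default here and raw
vectors are accepted by the same function. ΔF/F₀ is primarily the fold
change F/F₀ with F₀ the mean of the first 60 s — a constant trace sits at
1 — with (F−F₀)/F₀ exported alongside.

Group statistics are classic: mean ± SEM, pooled-variance Student's t by
default (Welch by flag, since group variances visibly differ between
phenotypes), one-way ANOVA with Tukey HSD. Type-I error calibration at
α = 0.05 over 10,000 null simulations is part of the acceptance checks.

## The synthetic generator

The generator is deliberately phenomenological — spike templates on a
two-state baseline — not a conductance-based neuron model. The artifact
under test is the analysis pipeline, and that requires *exact* planted
truth: every spike time, burst interval and plateau amplitude the generator
emits is recorded and returned.

* **Pacemaker mode** (control-like): a Gamma renewal process (mean
  1/`pacemaker_rate_hz`, CV directly configurable) emits single spikes;
  each event is, with probability `small_burst_prob`, replaced by a small
  burst of 3–8 spikes at ~15 Hz over a modest depolarization.
* **Bursty mode** (triplication-like): a semi-Markov alternation of
  up-states (truncated-normal durations, default mean 11.2 s, bounds
  5–25 s) carrying Gamma-jittered spiking at `burst_rate_hz` (default
  11.6 Hz) on a square plateau with 10-ms cosine edges, and pauses with
  sparse Poisson singles. Published sources do not quantify the pause
  lengths; the default (mean 40 s, bounds 10–80 s) reproduces the
  qualitative long-pause phenotype at an overall rate near the published
  ~2.5 Hz, and is labeled an assumption.

Intra-burst ISI draws are kept consistent with the burst rule the package
plants as truth: the first ISI of a planted burst is drawn below the 80-ms
onset threshold and subsequent ISIs below the 160-ms continuation bound
(rejection sampling). Without this, a planted "burst" could legitimately be
classified as opening a few spikes late, and the planted membership would
not be a valid oracle for the rule. ISIs are additionally floored at the
spike-template support so templates never overlap; configurations whose
requested rates violate that floor are rejected with an error.

Spikes are rendered from a Gaussian template (configurable amplitude and
FWHM) snapped to the sample grid, so the planted peak sits exactly on a
sample. Real action potentials are asymmetric and sharper at the peak than
a Gaussian of equal FWHM; consequences: measured half-widths sit slightly
below the template FWHM (the half level is referenced to the dV/dt
threshold, not the baseline), and peak-time jitter under noise is slightly
worse than for real spikes. Neither affects the planted-truth accounting.

What the generator does **not** emulate: channel noise structure (noise is
white Gaussian), spike-height adaptation and depolarization block within
bursts, series-resistance and liquid-junction artifacts, slow drift, or any
receptor-kinetics mechanism behind the drug scenarios (regime switches are
instantaneous parameter changes). Passing tests therefore demonstrate that
the pipeline measures what it claims on well-posed inputs with realistic
firing statistics — not that it is robust to every pathology of real
recordings.

The group presets encode the published anchors as generator parameters:
pacemaker ~1 Hz with ~29% of spikes in small bursts over 5.91 mV
(control-like human), 11.6 Hz bursts over 14.13 mV (triplication-like
human), and the corresponding mouse pair (4.88 / 10.54 mV). The
`ast-quinpirole` preset switches the bursty regime at 150 s to a pacemaker
regime anchored to the reported agonist effect (≈1.8 Hz, ≈49% SWB, 5.4 mV);
`ast-sulpiride` switches to identical parameters — a true null.

## Problem sizes and determinism

Default synthetic recordings are 2 min at 10 kHz; drug-scenario recordings
are 5 min. Cohort analyses in the tests and the acceptance script use 12
neurons per group, 20 seeds for recovery sweeps, 1,000 random trains for the
burst-rule oracle and 10,000 null simulations for test calibration — sizes
at which the Monte-Carlo error of every asserted quantity is comfortably
inside its tolerance.

All randomness flows through explicit integer seeds; a fixed configuration
yields bit-identical traces, and `run_pipeline()` with a fixed `run_config`
yields byte-identical result files (numbers are serialized at 9 significant
digits; the provenance record contains no timestamps). Input files are
identified by MD5 in the provenance JSON.

## Known limitations

* The burst rule is the 80/160 ms ISI rule only; Poisson-surprise,
  rank-surprise and hidden-Markov segmentation are deliberately out of
  scope.
* "Spike half-amplitude" as printed in some figure panels (≈35 mV, ≈29 mV)
  has no published definition; the package reports amplitude and
  amplitude/2 separately and does not claim to reproduce that quantity.
* The reader accepts two-column delimited text (and the package's own CSV
  output); proprietary binary acquisition formats are out of scope for the
  core and would enter behind the same `read_trace()` contract.
* Neurons are treated as independent replicates (as in the source
  analyses); no mixed-effects modeling of neurons within differentiations
  or cultures.
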