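---
title: "Methods: semi-automated seizure detection and excitability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated seizure detection and excitability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogseize)
```

# Scope

`ecogseize` packages the analysis stack used around chronic-epilepsy gene-therapy
experiments in rodents: a semi-automated seizure detector for single-channel
wireless ECoG telemetry, an automated current-clamp analysis, an activity-clamp
(dynamic-clamp) simulator, and the behavioral and molecular summary statistics
of such studies. Every input the pipeline consumes can be generated
synthetically with known ground truth, so each analysis step is validated
against an independent oracle rather than against itself.

# The seizure detector

## Model

Recordings (256 Hz, band-limited 1–160 Hz) are divided into consecutive 5-s
chunks; a trailing partial chunk is dropped so every feature vector describes
exactly `5 * fs` samples. Each chunk is mapped to a 15-dimensional feature
vector and classified as *ictal* or *interictal* by a class-weighted random
forest. The discrete chunk predictions are then smoothed with a two-state
hidden Markov model: the hidden states are the human annotations, the
emissions are the classifier outputs, and the per-chunk marginal posterior
$\gamma_t(s) = P(S_t = s \mid o_{1:n})$ is computed with the forward–backward
algorithm using per-step scaling, so sequences of $10^6$ chunks (weeks of
telemetry) do not underflow. Chunks with $\gamma_t(\text{ictal}) \ge 0.5$
are merged into candidate events; gaps of at most one chunk are bridged.
Candidates are exported as an editable CSV for manual verification, and the
re-imported table becomes a `provenance = "verified"` annotation set — the
detector is semi-automated by design, and human boundary edits (including
boundaries off the 5-s grid) always win.

The HMM is **not** fitted by expectation–maximization. Its transition matrix
comes from add-one-smoothed transition counts of the annotated label
sequences, the emission matrix from add-one-smoothed confusion counts of
session-grouped cross-validated classifier predictions against the
annotations, and the initial distribution from smoothed state frequencies.
Add-one smoothing keeps every entry strictly inside $(0,1)$: a training
corpus with no observed ictal-to-ictal transition must not produce a model
that forbids remaining in a seizure.

Cross-validation folds are whole sessions. Adjacent chunks of one session are
strongly dependent; chunk-level folds would leak that dependence across the
train/test split and overstate the emission quality that parameterizes the
HMM.

## The 15 features

The canonical feature set covers amplitude (coastline, variance, RMS,
peak-to-peak, 95th percentile of absolute amplitude), waveform shape
(skewness, excess kurtosis, zero crossings), and spectrum (integrated power
in 1–4, 4–8, 8–12, 12–30, 30–70 and 70–120 Hz, plus spectral entropy).
The exact catalogue used in any one laboratory varies, so the set is
pluggable: `extract_features()` accepts any named list of
`function(x, fs)` features, and a model trained with a substituted
catalogue carries it through detection. Spectral estimates use Welch
averaging with 1-s Hann segments at 50% overlap — nine segments per chunk,
a stable estimate at the 5-s horizon. Degenerate inputs follow a fixed
convention: skewness, kurtosis and spectral entropy of a constant chunk are
0, so feature vectors are finite for any finite input. Per-feature z-scoring
parameters are estimated on the training library, stored with the model, and
applied at prediction time.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| chunk length | 5 | s | granularity of labels and events |
| forest size | 100 | trees | stable probabilities at 2–3k training chunks |
| cross-validation folds | 5 (session-grouped) | — | leakage control |
| HMM smoothing | 1 (add-one) | pseudo-count | keeps all rates inside (0,1) |
| posterior threshold | 0.5 | — | symmetric loss on chunk labels |
| gap merging | 1 | chunk | one misclassified mid-seizure chunk must not split an event |

The posterior threshold and gap merge are deliberate knobs: a screening
deployment can lower the threshold and widen the merge to push the false
negative rate down at the cost of more candidates for review.

# What the synthetic data emulate — and what they do not

The ECoG generator produces Gaussian background noise with a $1/f^\beta$
amplitude spectrum band-limited to 1–160 Hz (default $\beta = 1$), scaled to
a background RMS, with seizures injected as rhythmic discharges: a 5 Hz base
oscillation plus attenuated second and third harmonics under a raised-cosine
amplitude ramp of up to 1.5 s at each end, scaled so the ictal-interval RMS
is close to `ictal_amplitude_ratio` (default 6) times background. This gives
the classifier a realistic spectral and amplitude contrast and gives every
test exact event boundaries.

It does **not** model chemoconvulsant electrographic seizures: no spike-wave
morphology evolution, no postictal suppression, no movement or electrode
artifacts, no inter-animal variability. A detector that passes the held-out
sensitivity check here is validated as an *implementation* (features,
forest, smoothing, event assembly are internally consistent and recover
planted ground truth); its clinical-grade performance on real telemetry
still depends on a representative training library, which is why the review
export/import loop is part of the surface.

The acceptance-scale audit trains on three hour-long sessions (20 seizures
each) and scores six independent hour-long sessions holding 300 planted
seizures — nine hours of 256 Hz signal in total, a deliberately compact
analogue of an eight-week audit: large enough that one missed seizure is
resolvable as a 1/300 rate, small enough to run routinely.

# Current-clamp analysis

Action potentials are detected on the criterion pair: an upward 0 mV
crossing whose preceding rising phase reaches dV/dt > 20 mV/ms, with no new
event until the trace falls back below 0 mV, applied to sweeps with injected
current in 0–500 pA. dV/dt uses central differences; the AP threshold point
is the earliest sample of the contiguous run at or above 20 mV/ms found by
searching backward from the crossing. Half-width is the full width at half
of the threshold-to-peak amplitude with linear interpolation between
samples — the threshold-to-peak reference is one of several conventions in
use and is stated here because downstream comparisons depend on it.

Passive properties come from the step protocol (250-ms steps from −20 pA in
10 pA increments): per-step resistance is the steady-state deflection (mean
of the last 20% of the step) over the injected current; input resistance
averages the two most negative steps and the first subthreshold positive
step; tau is a single-exponential least-squares fit of the relaxation on the
largest hyperpolarizing step; capacitance is tau/R (ms/MΩ = nF, reported in
pF). The tau fit uses the whole step window rather than an early-time
window: with realistic 0.2 mV trace noise and small cells (1–2 mV
deflections) an onset-limited window leaves tau errors of several percent,
while the full window pins the plateau, averages the noise, and keeps
recovery within ~2% across an (R, tau) grid of 80–300 MΩ × 8–30 ms. A
63%-crossing estimate seeds the optimizer.

The model neuron behind all ground truth is an exponential
integrate-and-fire cell (forward Euler, 0.02 ms steps for 50 kHz-equivalent
sweeps) with an absolute refractory period and a stereotyped linear
repolarization whose rate is a parameter — so the half-width analysis has a
monotonic ground-truth knob. Spike *counts over a fixed window* are a step
function of integration accuracy: a spike can straddle the step end, so a
10×-finer integration can legitimately differ by one count near threshold.
The validation therefore asserts exact agreement on strongly suprathreshold
steps and a ±1 bound elsewhere.

# Activity clamp

The simulator reproduces the conductance-injection computation of a dynamic
clamp: at every step of a closed loop running at the clamp iteration rate
(15 kHz), the command current is
$I = g_\mathrm{exc}(E_\mathrm{exc} - V) + g_\mathrm{inh}(E_\mathrm{inh} - V)$
with set reversals 0 mV (excitatory) and −75 mV (inhibitory) corrected for a
14.9 mV liquid junction potential. The correction is applied as
$E_\mathrm{eff} = E_\mathrm{set} - 14.9$ mV — recorded potentials read more
depolarized than true — and both the magnitude and the sign convention are
configurable, since rigs differ in where they absorb the correction.

Templates emulate a train of 24 epileptiform synaptic barrages: each burst
is a strictly unimodal alpha-function envelope (rise time one eighth of the
0.3 s burst window) with per-burst amplitude jitter, the inhibitory series
lagging by 5 ms, and both series normalized so their maxima equal the
requested peaks exactly. Unimodality is a deliberate simplification: it
guarantees exactly one above-5%-of-peak interval per burst, which keeps
burst counting unambiguous; real barrages have intra-burst structure this
template does not claim to reproduce. Default peaks (20 nS excitatory,
10 nS inhibitory) put the conductance threshold of the default cell near
scale 1, so threshold searches exercise both directions of the bracket.

The conductance threshold search brackets geometrically (doubling or
halving from scale 1, capped at 100) and bisects to 1% relative tolerance;
a fine-grid scan validates it. Forward Euler at the clamp rate is validated
against 4× refinement with a ±1 spike tolerance. A static potassium-like
conductance (reversal −90 mV) can be added to the cell; total spike counts
are non-increasing in that conductance across the tested grid, the
direction expected for increased K^+^ channel expression.

# Behavioral and molecular statistics

* **Discrimination index**: (altered − unchanged)/total exploration time;
  undefined (NA with a warning) when total exploration is zero.
* **ΔΔCT**: per-sample ΔCT = CT~target~ − CT~reference~; ΔΔCT relative to the
  mean control ΔCT by default, or to a within-pair control (`reference =
  "paired"`, e.g. contralateral hippocampus); fold = 2^−ΔΔCT^.
* **Fisher's exact 2×2 test**: two-sided p by explicit enumeration of all
  tables with the observed margins, summing hypergeometric probabilities no
  greater than the observed one; a 10^−7^ relative tolerance on that
  comparison absorbs floating-point ties. The implementation is validated
  against an independent factorial-formula enumeration for every table with
  n ≤ 40 and against `stats::fisher.test()`.
* **Cohort summaries**: seizures/day per phase; animals classified "fewer"
  vs "more_or_equal" after treatment by strict comparison of daily *rates*
  (ties count against "fewer" — the conservative choice when phase
  durations differ); inclusion flag at a baseline rate of one seizure per
  week; cumulative curves normalized to each animal's baseline total.

# Numerical choices and degenerate inputs

* Chunk windows are half-open `[i·L, (i+1)·L)` in samples and all interval
  I/O is half-open, 0-based seconds — boundaries never double-count.
* A chunk is ictal if it overlaps an ictal interval by any positive amount;
  no minimum-overlap fraction is invented.
* Constant chunks: moments and entropy return 0; z-scoring guards zero
  variance by unit scale.
* EDF storage quantizes to 16 bits over the observed physical range (error
  at most one quantization step); the CSV session dialect prints 17
  significant digits and round-trips bit-exactly.
* Every generator is a pure function of its parameters including the seed;
  the random forest is seeded and single-threaded, so training is
  reproducible end to end.

# Known limitations

* The detector assumes a single channel and a fixed sampling rate matching
  the training configuration; montages and resampling are out of scope.
* Emissions are discrete predicted labels. Probability-vector emissions
  would retain classifier confidence and are a natural extension.
* The model neuron is plumbing for validation, not a claim about any real
  cell class; activity-clamp results on it demonstrate the computation, not
  biology.
* The synthetic seizure morphology is stationary within an event except for
  amplitude ramps; detectors tuned on it will not have seen evolving
  discharge frequencies.
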