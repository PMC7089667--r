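# ecogseize

Seizure detection and neuronal-excitability analysis for chronic ECoG
telemetry in rodent epilepsy models.

Long-term wireless electrocorticography produces weeks of single-channel
signal per animal; finding every generalized seizure by eye does not scale,
and therapy studies live or die on the seizure count. `ecogseize`
implements the semi-automated detection approach used in such studies,
together with the cellular-excitability analyses that accompany them:

* **Seizure detector** — recordings are chunked into 5-s blocks, each block
  mapped to a 15-dimensional feature vector (coastline, moments, band
  powers, spectral entropy), classified by a class-weighted random forest,
  and smoothed with a two-state hidden Markov model whose hidden states are
  the human annotations and whose emissions are the classifier predictions.
  The forward–backward algorithm yields the per-chunk posterior
  γ<sub>t</sub>(ictal) = P(S<sub>t</sub> = ictal | o<sub>1:n</sub>); runs of
  above-threshold chunks become candidate events, which can be exported for
  manual review and re-imported as verified annotations.
* **Current-clamp analysis** — action potentials detected by the 0 mV
  crossing + dV/dt > 20 mV/ms criterion; firing curves, maximal rate and
  rheobase; input resistance from steady-state ΔV/ΔI, membrane time
  constant τ from an exponential fit of the voltage relaxation, and
  capacitance C = τ/R.
* **Activity clamp** — closed-loop injection of paired
  excitatory/inhibitory conductance templates
  (I = g·(E<sub>rev</sub> − V), reversals corrected for a 14.9 mV liquid
  junction potential) into a model neuron at 15 kHz, with per-burst spike
  counts and a bisection search for the conductance threshold of action
  potential generation.
* **Behavioral & molecular statistics** — discrimination index, ΔΔC<sub>T</sub>
  relative expression, an exact two-sided 2×2 Fisher test by hypergeometric
  enumeration, and cohort seizure summaries (seizures/day by phase,
  fewer-vs-more classification, baseline-normalized cumulative curves).
* **Synthetic data with ground truth** — every input above can be generated:
  1/f background ECoG with planted rhythmic seizures, current-clamp sweeps
  from an exponential integrate-and-fire cell with known R, τ and spike
  times, 24-burst conductance templates, and exploration logs. All
  validation runs against this known ground truth.

## Worked example

Train a detector on three synthetic hour-long sessions and score an
independent held-out hour:

```r
library(ecogseize)

training <- list()
for (i in 1:3) {
  ev <- sample_seizure_events(3600, 10, seed = 2 * i - 1)
  s  <- generate_ecog_session(
    ecog_gen_params(duration_s = 3600, seizure_events = ev, seed = 2 * i))
  training[[paste0("s", i)]] <- list(rec = s$recording, ann = s$annotations)
}
lib <- build_library(training)
lib
#> <seizure_library> 3 session(s), 2160 chunks (148 ictal / 2012 interictal)

fit <- train_classifier(lib, seed = 11)
hmm <- estimate_hmm_from_cv(fit$cv_predictions)
hmm
#> <hmm_parameters>
#> A (transition):
#>            interictal  ictal
#> interictal     0.9846 0.0154
#> ictal          0.2067 0.7933
#> B (emission):
#>            interictal  ictal
#> interictal     0.9990 0.0010
#> ictal          0.0333 0.9667
#> pi: 0.9311, 0.0689

ho <- generate_ecog_session(ecog_gen_params(
  3600, seizure_events = sample_seizure_events(3600, 12, seed = 7), seed = 8))
res <- detect(ho$recording, fit$model, hmm)
head(res$events, 3)
#>   start_s end_s
#> 1      40    70
#> 2     320   345
#> 3     395   415

evaluate_detections(res, ho$annotations, 3600)
#> <detection_metrics> 12/12 seizures detected (sensitivity 1, FN rate 0); 0 FP (0.00/day)
```

The emission matrix reads directly as classifier quality: an interictal
chunk is mislabeled 0.1% of the time, an ictal chunk 3.3% — and the
transition matrix encodes that seizures are rare (1.5% entry probability
per 5-s step) but persistent once entered. Events are reported in seconds
from session start on the 5-s chunk grid; `export_for_review()` /
`import_review()` close the loop with a human reviewer.

Cellular excitability from the same package, on a synthetic cell with
R = 150 MΩ, τ = 15 ms:

```r
cell <- model_cell_params(input_resistance = 150, membrane_tau = 15)
sw <- generate_current_clamp_sweeps(step_protocol(n_steps = 25), cell)
passive_properties(sw$sweeps)
#> <passive_properties> R = 150.0 MOhm, tau = 15.09 ms, C = 100.6 pF, Vrest = -70.0 mV
firing_curve(sw$sweeps)$current_threshold_pA
#> [1] 160
fisher_exact_2x2(8, 1, 5, 8)   # fewer-seizure proportions, treated vs control
#> [1] 0.03060593
```

## Command line

A thin wrapper over the package functions lives at
`inst/scripts/ecogseize-cli.R` (simulate sessions/templates/sweeps, train,
detect, evaluate, plus `fisher` and `di` one-liners):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "ecogseize-cli.R", package = "ecogseize"))')" \
  fisher 8 1 5 8
#> two-sided p = 0.0306059
```

## Package layout

* `R/synthetic-ecog.R`, `R/synthetic-cell.R` — generators with ground truth
* `R/ecog-io.R` — sessions (EDF / lossless CSV), annotations, chunking, the
  training library
* `R/features.R` — the pluggable 15-feature catalogue
* `R/hmm.R`, `R/detector.R` — HMM estimation, forward–backward, the
  detection pipeline, evaluation, review round trip
* `R/ephys.R` — AP detection, firing curves, passive properties
* `R/activity-clamp.R` — conductance injection, threshold search
* `R/behavior.R` — DI, ΔΔCT, exact Fisher test, cohort summaries

See `vignettes/seizure-detection-methods.Rmd` for the modeling choices,
their rationale, and known limitations.
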