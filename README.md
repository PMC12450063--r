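# gastricmill

Rhythm-state analysis of stomatogastric motor patterns from spike-time data.

The crustacean stomatogastric ganglion (STG) generates two interacting motor
rhythms: the fast (~1 s cycle) pyloric rhythm, paced by the PD neurons, and
the slow (~10–20 s cycle) gastric mill rhythm, expressed here as long
(≥ 1 s) IC neuron bursts with coordinated LG, DG and AM activity and
IC-timed interruptions of the pyloric rhythm. `gastricmill` is for
electrophysiologists who have already sorted their extracellular recordings
into per-neuron spike times and need to quantify these rhythms and compare
them across pharmacological or hormonal conditions.

## What it computes

* **Burst detection** by neuron-class interspike-interval ceilings: a gap
  > 2 s closes a burst for the slow gastric neurons (LG, DG, and IC in
  gastric context), a gap > 0.25 s for pyloric and gastropyloric neurons.
  Intraburst rate is (n − 1)/duration.
* **Cycles and interruptions.** Pyloric cycle period is the onset-to-onset
  interval of consecutive PD bursts; cycles with < 10 IC spikes define the
  control period, and a cycle at ≥ 150 % of the control mean is an
  interruption. Gastric cycle period is the interval between consecutive
  long IC burst onsets, with brief (1–2 s) "prepeak" bursts that precede a
  > 2 s burst by ≤ 5 s folded into the preceding cycle.
* **Rhythm-state classification.** Each 200-s segment (four per 900-s
  incubation, after a 60-s exclusion) becomes a 120-length feature vector
  (ISI and phase deciles, intraburst rate, ISI-order ratio, max-ISI ratio,
  burstiness per neuron), which is z-scored, projected onto 10 principal
  components and clustered with k-means (k = 3) into gastric mill rhythm
  (GMR), irregular, or no-rhythm states.
* **Phase profiles.** 100-bin spike histograms across the gastric cycle,
  normalized by bin duration, averaged cycles → segments → experiments →
  condition, with a bespoke per-bin significance heuristic (α = 0.01,
  difference from *both* other conditions, ≥ 2 consecutive bins).
* **Condition statistics.** GMR odds and odds ratios, cascading basic-method
  bootstrap CIs (95 % → 99.999 %), unbiased Cohen's d, rank-biserial
  correlation, Kendall's W, Cramér's V, repeated-measures correlation, and
  equal-slopes ANCOVA with Holm–Šidák pairwise testing.
* **Synthetic data.** `generate_recording()` emits labelled six-neuron spike
  trains under FULL / IRREGULAR / NONE rhythm states with full ground truth,
  so every stage is testable without raw recordings.

## Worked example

```r
library(gastricmill)

sim <- generate_recording(rhythm_spec("FULL", seed = 7), duration_s = 900)
summarize_incubation(sim$recording)[, c("n_long_ic_bursts", "n_interruptions",
                                        "gm_cycle_period_s", "ic_rate_hz")]
#>   n_long_ic_bursts n_interruptions gm_cycle_period_s ic_rate_hz
#> 1               70              94          13.96921   23.98265
```

Seventy long IC bursts were detected over the 840-s analysis window — exactly
the number the generator emitted — with 94 pyloric cycles delayed beyond
150 % of control, a mean gastric period of 14.0 s and a 24 Hz intraburst IC
rate, matching the simulated rhythm. Classifying a balanced batch:

```r
batch <- generate_condition_batch(6, mix = c(FULL = 1/3, IRREGULAR = 1/3,
                                             NONE = 1/3), seed = 31)
fb <- featurize_batch(lapply(batch, `[[`, "recording"))
model <- fit_cluster_model(fb$features, info = fb$info)
print(model)
#> <gm_cluster_model> 3 clusters on 10 components (94.9% variance)
#>   mapping: 1 -> GMR, 2 -> IRREGULAR, 3 -> NONE
#>   training sizes: 8, 8, 8
```

Odds of a gastric mill rhythm from published per-condition segment counts:

```r
counts <- gmr_segment_counts()
odds_and_or(c(38, 6), c(42, 22))$odds_ratio   # fed hemolymph vs 10 uM saline
#> [1] 3.31746
```

A 3.3-fold increase in the odds of a gastric mill rhythm in 1 µM peptide
with fed hemolymph relative to 10 µM peptide in saline.

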