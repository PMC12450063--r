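---
title: "Methods: quantifying and classifying stomatogastric motor rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and classifying stomatogastric motor rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastricmill)
```

## The measurement problem

The stomatogastric ganglion (STG) of decapod crustaceans produces two
nested motor rhythms. The pyloric rhythm cycles at roughly 1 Hz and is paced
by the PD neurons; the gastric mill rhythm cycles every 10–20 s and, in the
version this package targets, is organized around long (≥ 1 s) bursts of the
IC neuron, with LG, DG and AM firing in coordination and the pyloric rhythm
visibly delayed while each long IC burst is in progress. Given per-neuron
spike times, the analysis must (1) delimit bursts, (2) reconstruct both
cycle structures, (3) decide, for each 200-s stretch of an incubation,
whether a gastric mill rhythm, an irregular rhythm, or no rhythm was
present, (4) describe each neuron's firing as a function of gastric cycle
phase, and (5) compare conditions statistically. Everything downstream of
spike sorting is in scope; spike sorting itself is not.

## Burst definitions and their parameters

A burst is a maximal run of spikes in which no interspike interval exceeds a
neuron-class ceiling: 2 s for the slow gastric-mill neurons (LG, DG, and IC
when extracting its gastric-mill-timed bursts) and 0.25 s for pyloric and
gastropyloric neurons. The 2 s value is roughly twice the pyloric period
during the gastric mill rhythm; 0.25 s is roughly half the fastest pyloric
period. Both are exposed in `gm_config()` but rarely need changing. Two
numerical choices are deliberate:

* a gap *strictly greater* than the ceiling splits; a gap exactly equal
  keeps the run together ("no interval longer than" reads as ≤ allowed);
* bursts need at least 2 spikes, because the intraburst rate
  (n − 1)/duration is undefined for singletons; lone spikes are kept as a
  tonic set so the partition of the train is exact.

One property often claimed for such detectors — that raising the ceiling
can only reduce the number of bursts — is false in this form: two tonic
spikes can merge into a brand-new 2-spike burst as the ceiling rises. The
monotone quantity is the number of maximal gap-groups (bursts plus tonic
spikes), and that is what the property tests assert.

Long IC bursts are those lasting at least `long_ic_burst_min_s` (default
1 s, inclusive; the boundary convention is configurable because usage in the
field mixes "≥ 1 s" and "> 1 s"). A brief gastric-timed IC burst of 1–2 s
followed within 5 s by a burst longer than 2 s is a *prepeak*: it belongs to
the preceding cycle, is excluded from cycle-period determination, but still
counts toward burst-count, duration and rate statistics.

## Cycles, controls and interruptions

Pyloric cycles run from each PD burst onset to the next; gastric cycles from
each cycle-defining long IC burst onset to the next. All windows and cycles
are half-open `[start, stop)` so a spike on a shared boundary is counted
exactly once. IC spikes are assigned to pyloric cycles by the same half-open
rule, and member bursts to gastric cycles by the cycle containing their
onset (a burst truncated by a segment boundary is owned by the segment
containing its onset, so it is counted once).

The control pyloric period is the arithmetic mean over *all* cycles of the
incubation with fewer than 10 IC spikes — a whole-incubation baseline, not a
running one. A cycle at or above 150 % of that mean
(`interruption_threshold = 1.5`) is an interruption. Both the spike-count
cutoff and the threshold are configurable; the interruption count is
monotone non-increasing in the threshold and the control set monotone
non-decreasing in the cutoff, which the test suite asserts.

## Segment features and rhythm-state classification

Each incubation is analyzed from 60 s after onset (equilibration) in four
nonoverlapping 200-s segments, covering 800 of the remaining 840 s (95 %).
Per segment and per neuron (IC, PD, LG, DG, AM) the feature vector holds the
10 ISI deciles, the 10 deciles of spike phase relative to the
gastric-mill-timed IC bursting, the mean intraburst rate, the ratio of
second- to first-order ISI, the largest-to-second-largest ISI ratio, and a
burstiness metric (largest gap between consecutive sorted ISIs over the
larger member of that pair) — 24 features × 5 neurons = 120.

Three definitions here were genuinely open and are fixed as follows:

* **Deciles** means ten summary quantiles at p = 0.1 … 1.0 with linear
  interpolation (not nine cut points); this keeps the stated 24-per-neuron
  block length.
* **Second- to first-order ISI ratio** is not defined in the source
  literature available to us; the implemented contract is the mean absolute
  second difference of the spike times divided by the mean ISI, which is 0
  for perfectly regular spiking and grows with irregularity. It is an
  explicit stand-in and documented as such on `isi_order_ratio()`.
* **Undefined entries** (absent neuron, < 2 ISIs, no gastric cycles — e.g.
  every no-rhythm segment lacks phase features) are `NA` sentinels imputed
  at the dataset mean during z-scoring, i.e. z-score 0: such segments remain
  classifiable from their ISI structure without biasing any feature's scale.

Classification z-scores each feature with the sample SD (the population/
sample choice is unstated in the field; sample SD chosen), projects onto the
top 10 principal components, and runs k-means with k = 3, 50 restarts and a
fixed seed, keeping the best inertia. On the study's own data the top 10
components reportedly captured over 95 % of total variance; on synthetic
batches they capture ~89–95 %, so the fitted model records the fraction and
warns when it is at or below 95 % rather than failing. Clusters are mapped
to categories by an explicit rule (the original assignment was conceptual):
the cluster with the highest mean long-IC-burst count, tie-broken by lowest
gastric-period CV, is the gastric mill rhythm; the cluster with the lowest
count is no-rhythm; the remainder irregular.

An interpretable rule-based classifier validates the mapping: a segment is
GMR when it has ≥ 3 gastric cycles of mean period < 40 s, every cycle
contains at least one LG, DG and AM burst, and interruptions occur at least
once per gastric cycle on average; NONE when it has no long IC bursts;
IRREGULAR otherwise. The 40 s cutoff is the field's definition of an
irregular (slow) rhythm.

The 2-D embedding (`embed_2d()`) is classical metric MDS of the Euclidean
distances between retained-component scores — a deterministic projection
that preserves the distance structure the clustering actually used. It is
for visualization only and enters no test of record.

## Phase profiles and the consecutive-bin heuristic

Each gastric cycle is divided into 100 bins from one long IC burst onset
(bin 0) to the next. Counts are averaged across cycles within a segment,
normalized by the *segment's* mean bin duration (mean period / 100; per-cycle
bin durations are deliberately not used, since the normalization exists to
absorb period differences across incubations), then averaged across a given
experiment's GMR segments and finally across experiments within a condition.
Prepeak spikes are binned in the cycle the prepeak rule assigned them to.

Cross-condition comparison uses, per neuron, bin and condition, a
basic-method bootstrap CI (10,000 iterations by default) on the difference
of across-experiment means against each of the two other conditions, at
α = 0.01. A bin counts as different only when the condition differs from
*both* others, and only within runs of at least two consecutive bins
(~0.25 s of a typical cycle). This heuristic is not exact family-wise error
control; a null-simulation regression guard in the test suite bounds the
per-neuron rate of any flagged run at 15 %, run at a reduced scale (40 null
datasets of 8 experiments, 200 bootstrap iterations) chosen to keep the
default suite fast while still detecting a broken heuristic.

## Condition statistics

Odds of a GMR segment are GMR over non-GMR (irregular + none) counts; odds
ratios divide condition odds. The default CI is the Woolf log-normal method
with an optional Haldane–Anscombe correction; published CIs for such odds
ratios are not reproducible from printed counts by any single standard
method, so the CI engine is a documented choice and only the point estimate
is treated as a worked example. Recomputing the ratios from the published
segment counts gives 10.7 (unfed hemolymph vs 1 µM saline) and 61.2 (fed vs
1 µM saline) where 11.5 and 57.8 were printed — the package reports what the
counts imply; only the self-consistent 3.3 (fed hemolymph vs 10 µM saline)
is asserted in tests.

The bootstrap CI on mean differences uses the basic (reverse percentile)
construction and escalates 95 % → 99 % → 99.9 % → 99.99 % → 99.999 %,
stopping at the first level whose interval crosses zero. Cohen's d carries
the Hedges small-sample correction J = 1 − 3/(4 df − 1). Kendall's W is
tie-corrected via midranks; `friedman_with_w()` permits two-condition
designs, where the Friedman statistic reduces to a sign-test-like quantity.
The repeated-measures correlation fits y on x with subject intercepts and
takes r = sign(slope)·√(SSx/(SSx + SSe)). The equal-slopes ANCOVA tests the
interaction first, adjusts group means at the grand-mean covariate, corrects
pairwise tests by step-down Holm–Šidák (authored here; base `p.adjust` has
Holm–Bonferroni only), and implements the per-group "null line" comparison
literally as an independent-samples t test of common-slope predictions
against the baselines — an unusual construction retained by design, flagged
in the documentation as not being a standard lack-of-fit test.

## What the synthetic generator emulates — and what it does not

`generate_recording()` produces the three rhythm states with ground truth.
FULL draws gastric periods from a truncated normal (mean 14 s, CV 0.18 —
the reported regular-rhythm values; FULL requires a mean in 13–20 s), one
long IC burst per cycle (mean 2.5 s, clipped to 1.5–3.5 s) firing on a
jittered regular grid at 24 Hz (the reported range is 21–28 Hz), an LG burst
at cycle onset, AM co-extensive with IC, DG from the IC burst end to near
the cycle midpoint, a ~1.1 s pyloric rhythm with 20 % PD duty cycle, LPG in
antiphase with its duty doubling through mid-cycle, and a 20 % chance per
cycle of a 1–1.5 s prepeak. While a long IC burst overlaps a pyloric cycle
by at least 0.6 s, that cycle's period is multiplied by the interruption
factor (default 1.8, comfortably above the 1.5 detection criterion so
recovery is exact). IRREGULAR uses mean period 45 s with CV 0.37 (the
reported irregular-rhythm CV), drops IC bursts intermittently and LG on
alternating cycles plus random DG/AM dropout — the structural LG alternation
guarantees every multi-cycle segment violates the GMR coordination rule, so
ground-truth labels and the rule-based classifier agree by construction.
NONE emits only pyloric-timed activity, with brief IC bursts every third
pyloric cycle: spacing them closer than the 2 s gastric ceiling would merge
the entire train into one spurious "long burst", and the field's burst
definitions implicitly assume IC's pyloric-timed activity is sparse outside
the rhythm.

Intraburst spiking is a jittered grid rather than a Poisson process: the
burst definitions are ISI ceilings, and regular 21–28 Hz spiking keeps the
operational definitions unambiguous (no noise model is stated for the real
data). Inter-burst gaps are floored so that detection, the prepeak rule and
the ground truth are mutually consistent. Consequently, passing recovery
tests shows the pipeline implements its definitions exactly on clean input;
it does *not* show robustness to spike-sorting errors, drifting baselines,
or neurons whose activity straddles the ceiling values — real recordings
will exercise those, synthetic ones cannot.

## Problem sizes and reproducibility

Default test and acceptance runs use 900-s recordings, batches of 6–20
subjects (24–80 segments), 200–2,000 bootstrap iterations in property
checks (10,000 in production settings), and 500-replicate coverage
simulations — sizes chosen so the whole suite completes in about a minute on
one core while leaving every statistical assertion comfortably powered.
Every stochastic stage draws from an isolated RNG stream seeded by
configuration (`gm_config(rng_seed = )`, `rhythm_spec(seed = )`, and per
subject `(global seed, subject index)`), restoring the caller's stream, so
batches are reproducible element-wise and pipeline reruns are bit-identical.

## Known limitations

* Segment-level summaries reported in the source literature (mean burst
  parameters per condition, phase-profile curves) depend on raw recordings
  and are mirrored in schema only, not in numeric value.
* The chi-squared distribution test refuses tables with a zero expected
  count rather than switching to an exact test.
* The basic bootstrap CI does not guarantee `low ≤ estimate ≤ high` for
  heavily skewed resampling distributions; this is inherent to the method.
* Spike-time precision is taken as given; no resampling-rate model is
  applied.
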