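---
title: "Methods: the oddwave simulation and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the oddwave simulation and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddwave)
```

oddwave implements a complete analysis chain for passive-listening auditory
oddball ERP experiments built on *identity difference waves*: designs in
which every stimulus serves as standard in one sub-block and as deviant in
the direction-swapped sub-block, so that the deviant-minus-standard
subtraction can be computed within physically identical stimuli and
low-level auditory responses cancel. The package was developed around a
Mandarin third-tone-sandhi design — a 2×2 within-subject crossing of *UR
relation* (whether standard and deviant conflict in underlying tone) and
*deviant sandhi status* (whether the deviant is underlyingly T2+T3 or
T3+T3) — but every stage is generic. This vignette documents the models,
the defaults and why they were chosen, the numerical decisions, and what
the synthetic-data generator does and does not emulate.

## The experimental design

`condition_catalog()` encodes the eight sub-blocks: four blocks (A–D), each
presented in an Original and a Reversed direction with standard and deviant
lexemes swapped. Each of the four conditions of the 2×2 design is realized
twice, once per direction. A sub-block holds 400 trials with 12.5%
deviants (50), drawn from four F0-trajectory renditions of the standard and
of the deviant lexeme (16 tokens in total; S1 390 ms, S2 430 ms).

`generate_sequence()` produces constrained pseudo-random trial orders:

* The number of standards before each deviant (including the first) is
  5–9. These gaps are realized by shuffling a *balanced multiset* — for 50
  deviants, exactly ten gaps of each length, which sums to the 350
  standards a 400-trial sub-block requires. Balancing, rather than i.i.d.
  sampling of gap lengths, is forced by the arithmetic: i.i.d. gaps hit
  the exact trial total with negligible probability, while the balanced
  multiset realizes the intended uniform 20% frequency per gap length
  exactly. (For deviant counts not divisible by 5 the flattest feasible
  multiset is adjusted to the required sum.)
* A standard token may not occur more than three times in succession; a
  deviant interrupts any such run. The "no deviant more than twice before
  another deviant" constraint is interpreted as: the same deviant token may
  occupy at most two *consecutive deviant slots*.
* Inter-stimulus intervals are drawn uniformly from 700–900 ms in 50 ms
  steps.

`validate_sequence()` re-checks every constraint independently of the
generator and names the rule and trial position of each violation; the
generate→validate round trip is exercised over a thousand seeds in the test
suite.

## Montage and adjacency

`build_montage()` places electrodes on a spherical head whose radius is
`circumference / (2π)` (8.913 cm for the 56 cm default). The built-in
idealized coordinate table follows the classic 10-20 construction: the
outer 10% ring at 92° inclination (the conventional just-below-equator
placement of spherical head models), the midline F/C/P row at 45°, the
FC/CP row at 22.5°, and intermediate electrodes (F3, FC3, …) as unit-sphere
arc midpoints of their row neighbours. Legacy labels T3/T4/T5/T6 resolve to
T7/T8/P7/P8. AFz is treated as ground and excluded from the default
31-channel set (configurable).

`build_adjacency()` links electrode pairs within a distance threshold
(default 6.02 cm). The default metric is the 3D chord distance; geodesic
(along-scalp) distance is available as an option. The chord metric with the
frozen coordinate table was calibrated once, before any test was written,
against the published summary of this cap/threshold combination — a mean of
3.1 neighbours per electrode (SD 0.9); the frozen construction gives
3.097 (SD 0.908). The same graph defines spatial connectivity for cluster
formation and the neighbourhoods for channel interpolation.

## The forward model (synthetic data)

`simulate_subblock()` builds every trial as a sum of ERP components, each a
Gaussian in time multiplied by a Gaussian spatial falloff over chord
distance from its centre electrode. Both kernels are normalized to unit
peak, so a component's `amplitude` is the literal peak voltage at its
centre electrode and peak latency — point measures are peak-referenced, so
this convention keeps the configuration interpretable. On standards, every
component is scaled by `habituation_factor` (default 0.6), and trial `i` of
`n` is scaled by `1 + ramp_gain * i / n` (default 0.3), planting the
second-half-stronger-than-first-half growth that split-half analyses probe.

The default component set (`default_components()`) realizes a
three-component summation account of the S1–S2 transitional positivity:

| component | applies to | peak (ms) | peak µV | spatial SD (cm) |
|---|---|---|---|---|
| mapping positivity | every underlyingly-T3+T3 token, both roles | 315 | 1.0 | 6 |
| UR-mismatch positivity | deviants of conditions 3–4 | 345 | 2.0 | 6 |
| base positivity | all deviants | 372 | 2.0 | 6 |
| segmental MMN | condition-1 deviants | 269 | −1.5 | 5 |
| early negativity | condition-2 deviants | 120 | −1.0 | 5 |
| S2 negativity | all deviants | 625 (sandhi) / 645 | −2.2 (UR-match) / −1.1 | 8 |

All components are centred at FCz (fronto-central topographies). The
summation reproduces the qualitative structure the design probes: condition
1 carries the base positivity only; condition 2 adds a habituation residual
`(1 − habituation_factor) ×` mapping positivity (the mapping component is
present in both roles of a sandhi sub-block, so only the habituation
residual survives the identity subtraction); condition 3 adds the full
UR-mismatch positivity; condition 4 carries all three. Sandhi conditions
therefore peak earlier, UR-mismatch conditions are larger and earlier, and
the derived waves #5 and #6 contain a planted transitional positivity.

Latency orderings (mapping < UR-mismatch < base), the 269 ms MMN peak, the
~53 ms onset / 120 ms peak of the condition-2 early negativity, the
amplitude relations (mapping smallest; UR-mismatch ≈ base), and the
S2-negativity modulation pattern are the anchored design facts. The
*absolute* amplitudes and spatial extents are a plausible preset, fixed
once so that the noise-free, all-electrode window means land in the
magnitude range such studies report (e.g. S2-negativity window means of
−0.71/−0.36 µV for UR-match/UR-mismatch; a mismatch-minus-match
transitional amplitude gap of ≈0.5 µV; a signed-area ratio of ≈2). They are
configuration, not canonical values.

Noise is an equal mixture (configurable) of white and 1/f-shaped Gaussian
noise at 8 µV total SD per channel and sample, optionally smoothed across
adjacency-graph neighbours (kernel `I + 0.5A`, rows scaled to unit L2 norm
so the marginal SD is preserved). The 1/f process is synthesized by the
classic six-pole parallel one-pole ("pink filter") approximation in
compiled code, with the filter state initialized from its exact joint
stationary distribution — no warm-up transients — and scaled by the
analytic stationary SD; its periodogram slope is ≈ −1. Between-participant
variability is a lognormal amplitude gain (SD 0.2) and a common latency
shift (SD 8 ms) per participant, drawn from participant-keyed streams so a
participant keeps the same "physiology" across sub-blocks. All randomness
derives deterministically from `cfg$seed` via per-(participant, sub-block)
counters.

`inject_artifacts()` plants three artifact classes at `artifact_rate`
(default 2%): frontal >100 µV blinks on 1–3 channels (interpolable),
the same deflection on ≥4 channels (forces rejection), and a
variance-inflated channel (caught by the 5-SD rule). Deflections are
centred in 150–900 ms so the pre-stimulus baseline stays clean; the
injection log is kept in `trial_meta` so preprocessing decisions can be
scored against ground truth.

What the generator does *not* emulate: real ocular/EMG artifact morphology,
non-spherical head geometry, volume-conducted correlated sources, drifts
and non-stationarities, or the auditory stimuli themselves. Passing tests
on synthetic data therefore demonstrate that the pipeline's algebra,
statistics, and bookkeeping are correct and that planted effects of
realistic size are recovered — not that any scientific claim about real
EEG holds.

## Preprocessing

`preprocess_epochs()` chains: re-referencing to the mastoid average (the
simulator carries M1/M2 as near-zero-signal channels so this stage is
exercised), a zero-phase 4th-order Butterworth low-pass at 30 Hz,
baseline correction over the −300–0 ms window, and artifact handling. The
filter is applied forward–backward (compiled recursion with odd-reflection
padding; a spectral implementation of the identical squared-magnitude
response is available as `method = "fft"`); DC gain is 1 and the two-pass
response at twice the cutoff is ≈ −48 dB.

`reject_and_interpolate()` marks a channel within a trial as bad when its
absolute voltage exceeds 100 µV, its within-trial range exceeds 100 µV, or
its trial variance lies more than 5 SDs from that channel's across-trial
variance distribution. The "extreme distribution" statistic is not uniquely
defined in common practice; per-channel trial variance z-scored across
trials was chosen as the simplest statistic that catches a noisy channel
without reacting to a single spike (the absolute rule already does that).
Trials with more than three bad channels are rejected; otherwise bad
channels are replaced by inverse-distance-weighted averages of their good
adjacency neighbours (all good channels if no neighbour is good) — a convex
combination, so interpolated samples are bounded by the neighbours'
extremes. Every decision, with the rule(s) that fired, is returned in the
report.

## Difference-wave algebra

`average_condition()` averages retained trials; collapsing across stimulus
sets weights by retained-trial counts (`pool_erps()`), so the result equals
the average over all underlying trials. `identity_difference()` subtracts a
stimulus set's standard average (from the direction-swapped sub-block) from
its deviant average and refuses mismatched token sets, so a non-identity
subtraction cannot masquerade as an identity one. The two
directions of a condition are collapsed by an *unweighted* mean
(`collapse_waves()`): the directions carry equal design weight, and no
convention for trial-count weighting at this level is established, so the
symmetric choice was taken. All algebra is done per participant before any
group statistic, mirroring the participant-level permutation units.

`derive_waves()` produces the effect waves: #5 = #3 − #1 and #6 = #4 − #2
(UR-relation effect within each deviant type), #7 = #2 − #1 and
#8 = #4 − #3 (sandhi-status effect), and the interaction wave #9, which is
computed as #8 − #7 and algebraically equals #6 − #5 and
(#4 + #1) − (#3 + #2); the three routes agree to machine precision and the
tests assert it.

## Cluster-based permutation test

`cluster_test()` is a one-sample spatiotemporal cluster-mass permutation
test across participants. Per point, a one-sample t statistic; points with
|t| above the critical t at `cluster_forming_alpha` (default 0.05,
two-tailed for two-sided tests, df = n − 1) are clustered. Connectivity is
spatial neighbours at the same sample plus the same channel at adjacent
samples — no diagonal space–time links, the standard definition. Clusters
contain same-sign members only, and one-sided tests form clusters only from
the hypothesized sign. A cluster's mass is the sum of its member t values;
its reported range is the min/max member time.

The null distribution flips the signs of whole participants' waves
(exploiting that second moments are sign-invariant, so each permutation
costs one matrix product) and records the maximum cluster |mass|;
p-values use the add-one estimator `(1 + b) / (1 + m)`, with ties counted
as exceedances (the identity assignment recurs among random sign vectors
and equals the observed mass exactly). Participants entering the null
stream are ordered canonically so results are invariant to input order.
The default is 5000 permutations. Correctness is pinned by an exhaustive
sign-flip enumeration oracle at n = 10 (all 1024 assignments) and by an
empirical type-I error of 0.05 ± 0.02 over 1000 null replicates.

`windowed_scan()` runs independent tests over a list of windows (the
canonical six 150 ms windows, for instance) and supports the
boundary-adjustment workflow: when a significant cluster touches a window
bound, the window is re-tested once, shifted toward that bound.

## Point measures and inference

`measure_wave()` computes, per electrode and after 2× linear-interpolation
up-sampling (damping high-frequency noise influence): the window mean
amplitude; the signed area (trapezoid integral of polarity-matching samples
only, carrying the polarity's sign); the fractional pre-peak latency
(walking backward from the polarity's extremum to the latest crossing of
`fraction` × peak, linearly interpolated; the window start is returned and
flagged when no crossing exists); and the fractional area latency (the time
at which the cumulative gated area reaches `fraction` of its total,
linearly inverted within a sample). A window containing no sample of the
required polarity yields flagged `NA` latencies, not an error. The default
windows are 250–400 ms (transitional positivity, positive polarity) and
550–700 ms (S2 negativity, negative polarity). Measures are validated
against closed-form triangle/rectangle cases and a 1000× dense-grid oracle.

`two_by_two_inference()` tests the two main effects and the interaction.
The default fits a linear mixed model (random slopes for both factors by
participant, automatically reduced to a random intercept on convergence
failure or singular fit; Satterthwaite F-tests; Bonferroni-adjusted
pairwise post-hoc contrasts), with electrodes entering as replicate
observations clustered within participants. A deterministic
`method = "cell_means"` alternative aggregates to participant × condition
cell means and runs exact paired contrasts; on noiseless balanced data its
interaction estimate is exactly `(m4 − m3) − (m2 − m1)`. `split_half()`
compares measures from the first and second half of each sub-block with a
paired test.

## Problem sizes and numerical choices

The package-level simulations (tests, examples) run the full design — 29
participants × 8 sub-blocks × 400 trials — at 250 Hz sampling, the
package's chosen analysis scale: the slowest component kernels (SD ≥ 30 ms)
and the 30 Hz low-pass make 250 Hz a faithful decimation of the 1 kHz
acquisition default, and it keeps a full-study simulation around eight
minutes on one core. The end-to-end recovery suite uses 1000 permutations
per cluster test (the `PermConfig` default remains 5000); the type-I-error
suite uses 1000 single-channel replicates at 500 permutations.

Other numerical conventions: epochs span −300–1200 ms inclusive
(`span × rate / 1000 + 1` samples); p-values are bounded below by
`1/(n_permutations + 1)`; zero-variance/zero-mean points contribute t = 0;
interpolation weights use `1/max(d, 1e-9)`; all container round-trips
(montage TSV/BESA text, epochs TSV + JSON, waves TSV + JSON sidecar,
BrainVision export, BIDS-style events.tsv) are plain text.

## Known limitations

* The spherical montage is idealized; digitized positions and realistic
  head geometry are out of scope, as is source localization.
* Artifact handling is threshold-based by design; ICA-style decomposition
  is not provided, and the synthetic artifacts are built to be caught by
  the threshold rules.
* The mixed-model path does not model electrode as a crossed random
  effect; electrodes are replicates within participants (a configurable
  subset can be measured instead).
* The generator's between-participant variability is a two-parameter
  summary (gain + latency shift); real between-subject topographic
  variability is richer.
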