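---
title: "Methods: microstates, phase-slope connectivity and graph metrics for decision EEG"
author: "eegdecide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

The package targets a common experimental design in affective neuroscience:
subjects complete several blocks of a timed decision task, each block
preceded by an emotional stimulus (or none), while multichannel EEG,
decision accuracy/reaction time, and pre/post valence self-reports are
recorded. Three questions drive the analysis chain:

1. Which quasi-stable scalp topographies (ERP microstates) organize the
   evoked response during the decision window, and are they shared across
   emotional conditions?
2. Do the emotional conditions modulate early evoked components —
   specifically the frontal P2 — in amplitude or latency?
3. Do graph-theoretic summaries of directed (effective) connectivity
   predict behavioral performance across blocks?

Because raw recordings from such experiments are rarely shareable, the
package pairs every analysis stage with a synthetic-data generator whose
ground truth is planted and known, so each stage can be validated by
recovery rather than by eyeballing.

# The synthetic cohort

`synth_config()` fixes the design constants: 250 Hz sampling, four blocks
(`None`, `H`, `Q`, `T` — no stimulus, positive, fear, sadness), 40 trials
per block, 6.5 s per trial, and a 32-channel 10-20 montage by default (the
montage is configurable; the prefrontal set FP1/FPz/FP2/AF3/AF4 and the
midline Fz/Cz/Pz are mandatory because downstream stages address them by
name).

Each channel's background is spectrally shaped Gaussian noise with power
`~ f^-1` above 1 Hz (flat below 1 Hz to avoid the DC singularity), scaled
to 10 uV RMS — a typical broadband EEG amplitude. The generator draws the
spectrum directly (complex Gaussian bins with Hermitian symmetry) and
inverts once per cohort member, which is distributionally identical to
FFT-filtering white noise and considerably cheaper.

Evoked activity is planted as Gaussian-windowed half-sine bumps with fixed
scalp weightings:

* **P2**, frontal, 100 ms wide, amplitude and latency per condition. The
  defaults (H 6 > None 4 > T 3 > Q 2.5 uV; Q delayed to 205 ms vs
  175–185 ms elsewhere) encode the qualitative finding the ERP stage is
  meant to detect: positive emotion evokes the largest frontal P2, fear a
  smaller and later one.
* **P3**, fronto-central, 150 ms wide, 3 uV at 350 ms, shared across
  conditions.
* **N3**, frontal, -3 uV at 3350 ms — 350 ms after the second picture of
  the trial appears at 3.0 s.

Directed coupling is planted as additive delayed copies
(`target += gain * lag(source)`), by default a midline triangle Fz→Cz,
Cz→Pz (lag 5 samples, gain 0.8) and Fz→Pz (lag 10, gain 0.6). A delayed
copy guarantees a cross-spectral phase that rises with frequency, i.e. a
known positive phase-slope-index direction, and the triangle gives the
midline a nonzero clustering coefficient. Gains are jittered per block by a
lognormal multiplier (sd 0.5 on the log scale) so that planted connectivity
— and hence the graph metrics — genuinely varies across the 64 blocks of a
cohort.

Behavior ties the cohort together: per-block correct counts are drawn as a
mixture of the standardized designated graph metric and independent noise
at a target correlation (default -0.6), rescaled to mean 33 / SD 4 of 40
trials (values taken from the behavioral summary statistics of the kind of
experiment emulated; they rescale proportionally when shorter blocks are
simulated), rounded and clipped. Reaction times are Gaussian per condition
(means 496/472/446/460 ms, SD 147 ms). Valence is drawn per subject on the
1-9 scale with planted post-minus-pre shifts (+3 for H, -3 for Q, -2.5 for
T, 0 for None), rounded and clipped.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction and realistic source topographies, bad channels, line noise,
non-stationarity across a session, and subject-level heterogeneity of the
evoked shapes. Passing recovery tests on this data therefore validates the
estimators and their wiring, not robustness to real-world artifacts — the
preprocessing stand-ins below are explicitly scoped to the synthetic
setting.

# Preprocessing

The conditioning chain is deterministic: polyphase resampling (only when
the target rate differs), a zero-phase 4th-order Butterworth band-pass at
1–40 Hz, common-average referencing, epoching of the 0–3.5 s decision
window, and peak-to-peak rejection at 200 uV.

Two numerically equivalent band-pass implementations are provided.
`filtfilt` applies the high- and low-pass sections forward-backward per
channel. `fft` multiplies each channel's spectrum by the identical squared
Butterworth magnitude (on the bilinear-warped frequency axis, so it matches
the digital filter exactly); the two agree to ~1e-10 relative away from the
record edges, and the spectral version is roughly 5x faster on long
multichannel recordings, so the orchestrated pipeline defaults to it. Both
are zero-phase, which is what matters here: component latencies are
analyzed downstream and must not be shifted.

Artifact-correction algorithms that real data would need (artifact subspace
reconstruction, ICA-based ocular removal, bad-channel interpolation) are
deliberately replaced by the amplitude criterion: the synthetic data
contain no artifacts, and those algorithms would add unverifiable black
boxes. No baseline correction is applied — the epoch starts at stimulus
onset, and the planted templates are zero-mean outside component windows.

# ERP microstates

`gfp()` is the root mean square across average-referenced electrodes at
each instant; inputs that are not average-referenced are re-referenced
with a warning. Peaks of the GFP curve (strict local maxima, thinned to a
minimum spacing, larger peak wins) supply the high-SNR topographies for
clustering.

**T-AAHC.** Every map starts as its own cluster. At each step the cluster
contributing least GEV — the GFP-squared-weighted sum of squared spatial
correlations between member maps and the cluster template — is dissolved,
and each orphaned map is reassigned to the surviving cluster with the
highest spatial correlation. Templates are the polarity-sensitive mean (or
the first principal component under polarity invariance), unit-normalized.
A solution is recorded at every K in the scanned range on the way down.
Evoked (ERP) microstates default to polarity-sensitive treatment because
component sign is meaningful; polarity invariance is the convention for
resting-state data and remains available.

**Model selection.** K is chosen by the predictive-residual criterion
`CV = sigma_hat^2 * ((n-1)/(n-1-K))^2`, with `sigma_hat^2` the mean
variance left unexplained by projecting each map on its assigned template
and `n` the electrode count. The criterion is computed per condition
independently, so different conditions may legitimately settle on different
K — which is exactly what per-condition microstate counts look like in
practice.

**Back-fitting and matching.** Each timepoint of the (grand-average)
waveform is assigned to the template with maximal spatial correlation
(ties to the lowest template index, for determinism), and contiguous equal
labels merge into a segment table. Cross-condition correspondence is a
greedy one-to-one pairing by descending absolute spatial correlation
against the first condition's templates. Labels are invariant to global
scaling of the waveform, and GEV is non-decreasing in K for the nested
solutions — both are enforced by tests.

The pipeline clusters the per-condition grand-average ERP (rather than
concatenated single trials): single-trial topographies at these SNRs are
dominated by noise, and the grand average is the object the segmentation
describes.

# Effective connectivity

Cross-spectra are Welch averages over 50%-overlapping, Hamming-tapered,
per-segment-demeaned windows; epoched input contributes segments per trial
so no window spans an epoch boundary. The default segment length of 1 s
gives a 1 Hz grid, so even the delta band (1–4 Hz) holds multiple
consecutive bins — a requirement of the phase-slope sum. The cross-spectral
array is forced exactly Hermitian at construction (the BLAS product leaves
~1e-18 asymmetries otherwise), which in turn makes the PSI matrix exactly
antisymmetric with an exactly zero diagonal.

The phase slope index for band F is
`Psi_ij = Im( sum_{f in F} conj(K_ij(f)) K_ij(f + delta_f) )`, where both
`f` and `f + delta_f` must lie inside the band. It is left un-normalized:
the summed-product form is the quantity of interest, and normalization by a
jackknife standard deviation only rescales the adjacency that a percolation
threshold is about to sparsify anyway. Positive `Psi_ij` means *i* leads
*j*; the adjacency keeps the positive part and drops negative entries
(antisymmetry makes dropping and reversing equivalent — one stated rule is
kept). Epochs are pooled into one Welch average per block; per-trial PSI
followed by averaging is noisier at these segment counts.

# Graph metrics

Weak-component percolation finds the largest threshold that leaves the
giant component at its all-edges size; because the giant-component size is
monotone in the threshold, the scan is a bisection over the sorted unique
weights (the tests verify bisection equals the exhaustive scan). Weak
connectivity is the permissive reading appropriate to sparsified directed
graphs, which are rarely strongly connected.

Distances are reciprocal weights (`d = 1/w`, the convention of the
standard brain-connectivity toolboxes), shortest paths by Dijkstra per
source. Characteristic path length averages finite ordered pairs only and
reports how many pairs were finite; global efficiency counts disconnected
pairs as zero efficiency, so both conventions stay well-defined on
fragmenting graphs. The directed weighted clustering coefficient uses the
cube-root triangle intensity
`t_i = (1/2) [(W^(1/3) + W^T^(1/3))^3]_ii` over the reciprocal-corrected
denominator `(k_in + k_out)(k_in + k_out - 1) - 2 k_reciprocal`; the
reciprocal term is implemented as `a_ij * a_ji` (the standard form — the
printed formula in some sources repeats `a_ij`, which would be a typo, as
it double-counts nothing). Local efficiency computes shortest paths on the
subgraph induced by each node's neighbors (the node itself removed) and
shares the same denominator. All four metrics are checked to 1e-12 against
independently coded brute-force implementations (Floyd-Warshall, naive
triple loops) on random graphs.

# Statistics layer

The behavioral and subjective tests are thin, guarded wrappers over the
classical procedures: matched-samples t (two-sided, on post-minus-pre
differences), one-way ANOVA from between/within sums of squares, Welch t
for the group comparison (unequal variances is the robust default when
nothing is known about them), and Pearson r with the t-transform p-value.
Degenerate inputs (zero-variance differences, zero within-group variance)
return explicit, documented results instead of NaN. The accuracy split
takes the top and bottom k = 16 blocks by correct count with a
deterministic (subject, block) tie-break. Block-level records (n = 64) are
the units of correlation. p-values are reported uncorrected across
bands/metrics — matching how such tables are conventionally reported — and
a Benjamini-Hochberg helper is exposed for readers who want control of the
false discovery rate.

The pointwise ERP ANOVA tests every timepoint across conditions and
reports runs of significant points; runs shorter than 20 ms are discarded
because isolated flickers at 250 Hz are noise, and the object of interest
is a contiguous period. No across-time correction is applied by default,
for the same reporting-convention reason.

# Validation studies and problem sizes

`psi_direction_study()`, `microstate_recovery_study()`,
`erp_recovery_study()`, `calibration_study()` and
`endtoend_recovery_study()` are first-class, seeded package functions; the
test suite and the reproduction script both run them. Sizes were chosen
once, to keep a full validation run in the minutes range on one core while
leaving wide statistical margins:

* PSI direction: 100 two-channel systems of 120 s, lag 5 samples, SNR 1.
* Microstates: 20 repetitions of 60 maps over 32 channels from 3 planted
  orthogonal templates at 10% spatial noise, K scanned 2–8.
* ERP: 20 repetitions of 4 conditions x 40 trials, planted P2 amplitudes
  3 uV apart, unit trial noise.
* Calibration: 2000 null replicates per test at alpha = 0.05.
* End-to-end: 50 cohort runs with `validation_cohort_config()` — the full
  16-subject, four-block design at 250 Hz with the default planted
  effects, but a 19-channel montage, 10 trials per block, 4 s simulated
  trials (the analyses only consume the 0–3.5 s decision window) and
  theta-band connectivity only. These reductions shrink simulation cost by
  roughly an order of magnitude without touching any quantity the studies
  assert on; the planted correlation, noise levels and effect sizes are
  the generator defaults.

# Known limitations

* The synthetic background is stationary and artifact-free; robustness to
  real artifacts is out of scope by design.
* PSI needs adequate coherence inside a band to be directional;
  uncoupled channel pairs produce near-zero antisymmetric noise, and after
  the positive-part rule these noise edges populate the graph. The
  percolation threshold removes the weakest of them but graph metrics on
  weak-coupling data should be interpreted comparatively (across blocks),
  not absolutely.
* The CV criterion's channel-count correction assumes more electrodes than
  clusters (`n > K + 1`); very small montages cannot scan large K.
* `cpl()` on a graph with no finite off-diagonal distance is undefined and
  errors; the pipeline records NA for such blocks and excludes them from
  correlations.
* Reading EDF is not supported; recordings interchange as delimited
  matrix + JSON header (`write_recording()` / `read_recording()`).
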