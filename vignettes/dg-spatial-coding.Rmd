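---
title: "Quantifying spatial information in dentate gyrus calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial information in dentate gyrus calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgspace)
```

## The problem

Head-fixed mice walking on a textured treadmill belt provide a controlled
setting for asking how hippocampal dentate gyrus (DG) granule cells encode
position. Two-photon calcium imaging yields fluorescence traces
(neurons x frames, here 15 Hz) while a rotary encoder and RFID tags at
texture boundaries report the belt position. DG activity is sparse, and only
a subpopulation of active cells is spatially tuned, so the analysis has to
quantify information at two levels: single cells (tuning index, tuning-curve
shape, single-cell discriminability) and the population (decoding accuracy,
linear Fisher information, the role of noise correlations).

`dgspace` implements that pipeline end to end, together with a synthetic
session generator with known ground truth, so every stage can be validated
without any recorded data.

## The generative model behind the synthetic sessions

A session is built as:

1. **Trajectory.** Belt speed follows a slow AR(1) around 421 cm/min
   (sd 23 cm/min, correlation ~0.98 per frame), truncated at a positive
   floor, on a 180 cm belt with four 45 cm textures. The encoder stream and
   RFID events are emitted exactly as a rig would produce them, including
   optional per-tick noise and calibration (gain) error.
2. **Rates.** Each neuron has an event rate
   \(\lambda(x) = g\,G_t\,(B + A e^{k(\cos(\theta(x)-\varphi)-1)})\) with
   \(\theta(x) = 2\pi x/L\). Untuned neurons have \(A = 0\). The global gain
   \(g\) is the experimental dial: it stands in for the manipulation of
   adult-born-neuron (ABN) activity, which the underlying biology suggests
   acts multiplicatively on granule-cell responses.
3. **Shared gain.** \(G_t\) is a mean-one log-normal fluctuation driven by a
   single global latent AR(1) source (stationary log-sd 0.4, correlation
   time 3 s). It multiplies every neuron's rate and is the sole source of
   noise correlations. An i.i.d. per-frame multiplier would average out
   within a position bin; the few-second correlation time makes the induced
   mean pairwise noise correlation ~0.02-0.03, the magnitude typically
   reported for hippocampal and cortical populations. The true magnitude of
   shared lap-to-lap variability in DG is not known; this default is a
   deliberate choice and is exposed in the configuration.
4. **Calcium.** Events are Poisson per frame (\(\lambda \Delta t\)),
   convolved with a single-exponential kernel (\(\tau = 1\) s, instantaneous
   rise, 1 dF/F per event — red-sensor-like kinetics at 15 Hz), plus additive
   Gaussian noise (sd 0.05 dF/F). Raw fluorescence is emitted as
   \(F = F_0(1 + \mathrm{dF/F})\) so the dF/F recipe can be round-tripped.

Defaults: 100 neurons (sparse DG sessions have on the order of 90 active
cells), 30 laps, 30 % tuned, baseline \(B \in [0.02, 0.08]\) events/s,
amplitude \(A \in [0.5, 2]\) events/s, concentration \(k \in [2, 8]\).
All randomness flows from one root seed through named sub-streams
(`derive_seed`), so a config plus a seed reproduces a session bit for bit.

What the generator deliberately does **not** emulate: imaging artifacts
(motion, neuropil contamination beyond a fixed coefficient, bleaching),
multi-peaked or direction/speed-conditioned tuning, spatially structured
(limited-range) noise correlations, and remapping across sessions. Passing
tests on synthetic data therefore validate the estimators under the stated
model, not the biology of any particular dataset.

## Stage-by-stage choices

### Position reconstruction

Position is the cumulative encoder sum, resampled to frame times by last
observation carried forward (the encoder is a counter; interpolation would
invent motion). At each RFID event the estimate is re-anchored to the tag's
known position, choosing the unwrapped representative nearest the current
estimate so laps are never lost. A discrepancy smaller than one sample
increment is within the encoder's sampling resolution and is left alone —
this makes reconstruction exact for a drift-free encoder — while larger
discrepancies are corrected either as a hard reset (default) or linearly
back-distributed over the preceding segment (`drift = "distribute"`). With a
5 % encoder calibration error and tags every 45 cm, the residual error stays
below \(0.05 \times 45 = 2.25\) cm.

### dF/F

\((F - rF_{\mathrm{neu}} - F_0)/F_0\) with \(F_0\) a rolling 10th-percentile
baseline over 60 s, floored at a small positive constant; \(r = 0.7\) when a
neuropil trace is supplied, 0 otherwise. These are documented defaults: the
extraction tool that produces the raw traces is outside this package's
scope.

### Significant transients

Traces are low-pass filtered with a zero-phase (forward-backward)
third-order Butterworth at 2 Hz — low enough to suppress shot noise at 15 Hz
sampling, high enough to preserve red-calcium-sensor kinetics. The filter
uses odd-reflection padding so its settling does not distort the trace ends.
Transients start where the trace rises 2 sigma above a 30 s rolling-mean
baseline and end where it falls below 0.5 sigma; baseline and sigma are
re-estimated three times from the transient-excluded trace. Runs shorter
than 3 frames (0.2 s) are discarded. The rolling window (30 s), cutoff
(2 Hz), and minimum duration (3 frames) are package defaults chosen against
the ~1 s transient timescale; all are exposed.

Two consequences worth knowing. First, a 2-sigma rule genuinely fires on
pure noise — on filtered white noise it detects on the order of 15 events
per 2000 frames, consistent with run-length statistics; these false events
carry tiny integrals and contribute negligibly to the distance-normalized
activity. Second, iterative re-estimation can only shrink the residual sd,
so the threshold tightens across iterations.

Activity is the time integral of the significant-transient trace divided by
the distance traveled (dF/F·s per cm).

### Deconvolution and tuning index

Rates are the nonnegative innovations of the AR(1) calcium model
(\(\max(0, c_t - \gamma c_{t-1})/\Delta t\)); simple, linear on the positive
part, and exact on isolated kernels. The noise floor of each rate trace is
estimated from the negative half of the unrectified innovations, which
contains no signal by construction. Rates below 2 sigma of that floor are
zeroed; the cumulative thresholded rate per 100-bin position bin, normalized
to the time spent there, gives the occupancy-normalized tuning curve, and
the tuning index is the modulus of its mean resultant
\(\left|\sum_b w_b e^{i\theta_b}/\sum_b w_b\right|\).

Two normalization questions were genuinely open. (1) Dividing the per-bin
*mean* rate by occupancy a second time distorts the index wherever occupancy
is not perfectly uniform and breaks the closed-form oracles (uniform profile
gives index 0; a noiseless von Mises profile with \(k = 2\) gives
\(I_1(2)/I_0(2) \approx 0.698\)); the package therefore normalizes the
*cumulative* rate by time, which equals the mean rate. (2) The resultant is
normalized by \(\sum_b w_b\) so the index is bounded in \([0, 1]\) and
comparable across cells; the unnormalized variant is available via
`normalization = "sum"`. Frames with locomotion below 0.5 cm/s are excluded
from both numerator and occupancy.

### Von Mises fits

Lap-by-bin tuning curves (20 bins, unfiltered dF/F) are fitted with
\(B + A e^{k(\cos(\theta-\varphi)-1)}\) by bounded least squares
(\(A \ge 0\), \(k \in [0, 50]\); beyond \(k = 50\) the peak is narrower than
one bin). Initialization is multi-start (circular mean of the above-baseline
mass, a resultant-based \(k_0\), and rotated alternatives), refined by
Levenberg-Marquardt; ties are broken by lowest SSE then lowest \(k\). Flat
curves return \(A = 0\) with a degeneracy flag rather than an arbitrary
\(k\).

Goodness of fit is cross-validated: within each bin, 75 % of lap-samples
train and 25 % test, over 10 random stratified splits;
\(R^2 = 1 - ss\_res/ss\_tot\) with \(ss\_tot\) taken about the held-out mean
(the full-data mean is available as an option), averaged over splits and
clipped to \([0, 1]\) for reporting (the unclipped value is retained). A cell
is well fitted when \(R^2 > 0.5\). Peak width is the circular variance
\(V = 1 - I_1(k)/I_0(k)\), computed with exponentially scaled Bessel
functions so large \(k\) cannot overflow.

At 50 laps and high SNR the fits recover the generator's parameters with
mean errors of ~1.5 degrees in \(\varphi\) and ~9 % in \(k\); individual
cells can deviate more (Poisson counting noise, and 18-degree bins limit the
narrowest fields), which is why recovery guarantees are stated on means.

### Decoding and Fisher information

The decoder is multinomial logistic regression over 20 position bins on
per-frame unfiltered dF/F, with a ridge penalty fitted along a warm-start
path down to a fixed strength (`lambda = 0.01`); accuracy is the mean
held-out fraction correct over 10 random stratified 75/25 frame splits.
Chance is 1/20 = 5 %. To compare populations of different sizes, a fixed
number of neurons (default 42) is subsampled, by default over 10 draws whose
metrics are averaged; sessions with fewer neurons are flagged rather than
padded.

Fisher information is estimated as d-prime squared between adjacent bin
pairs (including the circular wrap; the pairing scheme is a package choice).
For the population, lap responses are projected onto the difference of the
two class weight vectors; for single cells the raw responses are used. The
small-sample correction
\(\hat d^2_{bc} = \hat d^2\,(2T - N - 3)/(2T - 2) - 2N/T\) (with \(N = 1\)
readout dimension and \(T\) laps per bin) makes the estimator unbiased for
Gaussian responses — nulls therefore average to zero and may legitimately go
slightly negative, and are reported as-is. Dividing by the squared bin width
gives information per cm².

The discrimination threshold converts information to an interpretable
distance: under the local Gaussian model \(d'(\delta) = \delta\sqrt{J}\) and
an equal-prior single-interval ideal observer is correct with probability
\(\Phi(d'/2)\), so the distance discriminated correctly 70 % of the time is
\(\delta^* = 2\Phi^{-1}(0.70)/\sqrt{J}\). The two-alternative convention
\(\Phi(d'/\sqrt 2)\) is available via `model = "2afc"`.

Noise-correlation surrogates permute lap order independently per neuron
within each position bin: marginals (hence tuning curves) are preserved
exactly, cross-neuron covariances are destroyed in expectation. The decoder
weights are *not* refitted on the surrogate; the comparison asks what the
same readout extracts once correlations are gone. Under the shared-gain
generator the correlated noise partially cancels along the fitted readout,
so shuffling can lower the projected information here — the sign of the
with/without-correlation difference depends on the correlation structure and
is not a fixed prediction of the pipeline.

### Group statistics

Cell-level metrics pooled across animals are compared with a two-level
bootstrap that respects nesting. Observed statistic: difference of condition
means. Null: animals from both conditions are pooled; per replicate and per
condition, each animal slot draws an animal with replacement from the pool
and then that slot's original number of values with replacement within the
sampled animal. Resampling a fresh animal per value would destroy the
cluster structure and is grossly anti-conservative under a nested null
(empirical type-I error above 0.5); the two-stage scheme is calibrated
(type-I ~0.04 at alpha = 0.05) with power above 0.9 for a shift of three
between-animal sd at five animals per group. The two-sided p-value carries a
continuity floor \(1/(n_{boot}+1)\), and a within-condition resampling
variant is available for sensitivity analysis. Bonferroni correction is
applied across metrics.

One limitation surfaced by the synthetic experiments: with the generator's
high signal-to-noise defaults, raising the gain moves the *tuning index*
only through finite-sampling effects, so that contrast is directionally
positive but small; activity, fitted amplitude, and Fisher information carry
the strong, testable gain effects.

## Problem sizes used in the checks

The automated checks run on deliberately small instances — sessions of
45-80 neurons and 15-21 laps (a 21-lap session is ~9 min at the default belt
speed), 10 animals per condition for group contrasts, 500 null datasets for
bootstrap calibration, 2000 bootstrap replicates per test (the test itself
defaults to 100,000) — sizes at which every stage's oracle bound is already
informative.

## Degenerate inputs and numerical conventions

* Constant traces: no transients, degenerate flag; all-zero raw traces give
  all-zero dF/F with a warning, not an error.
* Unvisited position bins are excluded from tuning vectors and
  cross-validation with a warning; all-zero thresholded rates give index 0
  with a degeneracy flag.
* Zero pooled variance skips a bin pair with a flag; non-positive Fisher
  information yields an infinite threshold with a warning.
* Positions live on the half-open interval \([0, L)\); a position exactly at
  \(L\) wraps to bin 0; angles are \(2\pi x/L\).
* The session container is a versioned single-file serialization with
  bit-exact round trips; a schema mismatch is an explicit error.
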