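---
title: "Models and methods behind sonirehab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sonirehab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sonirehab` implements the computational pipeline of a movement-sonification
rehabilitation study for the upper limb after stroke: mapping 3D hand
positions inside a training frame to musical events, scoring the smoothness
of vertical arm strokes from path curvature, modelling smoothness across
patients, sessions, groups and capture devices with Bayesian multilevel
regressions compared by PSIS-LOO, and quantifying cortico-muscular coupling
as the low-beta EEG–EMG weighted phase lag index with cluster-based
permutation inference. Because the patient recordings themselves are not
available in machine-readable form, every stage is validated against
synthetic data with known ground truth; this vignette explains the models,
the generators, and the design decisions taken where the published
description left room.

## The sonification mapping

The training frame is a 51 × 51 cm board divided into a 3 × 3 grid of
fields, with 51 cm vertical bars divided into six equal pitch intervals.
Axis conventions (the published description names the axes but not their
origin or direction) are: `x` left→right (timbre: clarinet, saxophone,
bowed string), `y` vertical (pitch), `z` proximal→distal (loudness), origin
at the patient-side left board corner. Fields are numbered row-major from
the patient's near-left corner.

Pitch intervals are half-open `[low, high)` with the top boundary closed, so
a hand at exactly 51 cm still sounds the top note. The default tuning keeps
the system's printed endpoints — c′ = 226.6 Hz at the bottom and a′ = 440 Hz
at the top — although 226.6 Hz is not the equal-temperament c′ (261.63 Hz);
we deliberately do not "correct" the endpoint, and fill the interior notes
(293.66, 329.63, 349.23, 392.00 Hz) from equal temperament anchored at a′.
The whole table is a parameter of `map_pitch()` and `sonify()`.

Loudness falls linearly from 0 dB at the proximal edge to −20 dB at the
distal edge; only monotonicity is documented for the original system, so the
20 dB range is our choice. Event discretization uses a hysteresis of 5% of
one interval height: a pitch change registers only once the hand has crossed
the boundary by that margin, which debounces sensor jitter without delaying
deliberate movements. Both values are tunable.

## Movement smoothness

Trajectories are resampled to a uniform 60 Hz grid (linear interpolation;
dropout gaps longer than 250 ms are flagged and excluded rather than
bridged), and segmented into upward and downward strokes at sign changes of
the 5-sample-smoothed vertical velocity. Candidate strokes must span at
least 30% of the bar height and 0.3 s; the original study segmented
manually, so these thresholds are documented defaults.

Per sample of a stroke the squared 3D path curvature is

$$\kappa^2 \;=\; \frac{|\mathbf v|^2 |\mathbf a|^2 - (\mathbf v \cdot \mathbf a)^2}{|\mathbf v|^{2p}},$$

with velocity and acceleration from central finite differences. The
published formula divides by the squared speed only (`p = 1`), which is
dimensionally inconsistent with a curvature (it does not pass the analytic
circle test); we read that as a typesetting loss of the cube and default to
`p = 3`, the standard squared geometric curvature `|v × a|²/|v|⁶` with units
cm⁻². The printed form remains available via `curvature_sq(, p = 1)`. Under
`p = 3` the statistic is invariant to traversal speed and shifts by exactly
`+2 ln s` when the path is scaled by `s`; both properties are tested on a
constant-speed circle, for which the per-stroke score
`median(−ln κ²)` equals `2 ln r` (4.605 for r = 10 cm).

Two numerical guards keep the log finite: samples slower than 0.5 cm/s use
the floor speed in the denominator (turning points), and κ² is floored at
1e−12 (straight-line segments); the fraction of clamped samples is always
reported. Positions are low-pass filtered (zero-phase Butterworth, default
5 Hz) before differentiation — finite differences amplify measurement noise
with the square of the sampling rate, and motion-capture noise would
otherwise dominate the curvature of any real or simulated recording. The
cut-off sits above the frequency content of the simulated sub-movements
(≲ 4 Hz) and well below the 30 Hz Nyquist of the 60 Hz grid.

`build_records()` centres the covariates as in the fitted models: group and
capture device as −0.5/+0.5, session at each patient's median modelled
session, the outcome z-scored across all records, and `pre.z` as the
standardized per-patient mean smoothness of the baseline session. One
reading ambiguity is whether the study's per-day smoothness entered the
models per stroke or as session averages; we model per stroke and let the
patient-level terms pool, the more granular of the two readings.

## The synthetic movement generator

Strokes are minimum-jerk quintics between the interval-centre heights of a
task's note sequence, with monotone runs of the sequence collapsed into
single legato strokes — an up–down scale is one upward and one downward
stroke, so the first daily task (four scales) yields 8 strokes. Straight
vertical paths have zero geometric curvature, so the ideal stroke carries a
small lateral bow (1.5 cm, half-sine squared) giving it the gentle curvature
of natural reaching and a finite clean-baseline score.

Sub-movement corruption superimposes Gaussian-bell displacement bumps on all
three axes: per axis the count is Poisson(corruption) and the peak amplitude
0.4·corruption cm (±50%), widths 6–15% of the stroke; bells are compactly
supported so endpoints are unchanged. Two capture dialects add measurement
noise: *inertial* (uniform 60 Hz, 0.05 cm noise) and *optical* (jittered
sample times, 0.08 cm noise, occasional 1–3-sample dropouts that are flagged
rather than deleted). Stroke duration defaults to 2 s — the study does not
state its distribution, so it is exposed as a parameter rather than asserted.

Median `−ln κ²` decreases strictly over the corruption grid {0, 1, 2, 4, 8}
for the inertial dialect; for the optical dialect the first step (0 → 1) is
masked by the higher noise floor and only the coarser grid {0, 2, 4, 8} is
reliably monotone. This is a known limitation of the generator, not of the
statistic: sub-centimetre corruption is simply below the optical noise
floor, which mirrors why capture hardware mattered in the real data.

The cohort generator inverts a corruption → smoothness lookup (per dialect,
rebuilt from 1,000 simulated strokes per release and shipped as
`inst/extdata/corruption_calibration.csv`) to realize per-patient-session
latent values: baseline + patient intercept + group effect (from session 1
on) + session slope + device offset. Session 0 is a pre-intervention
baseline session to which neither the group effect nor the slope applies;
`pre.z` is derived from it and session 0 is excluded from the modelled
records — otherwise the baseline covariate would absorb the treatment
effect it is supposed to adjust for. Effects are declared in outcome SD
units: the raw-scale unit is chosen so that the predicted total SD of the
per-stroke records (within-stroke spread from the calibration's working
region plus the injected latent variance) equals one unit, which makes an
injected 0.5-unit group effect recover as ≈0.5 on the z-scored outcome.
Default cohort: 14 + 14 patients, 15 sessions, group effect 0.5, session
slope 0, patient SD 0.1 plus persistent baseline SD 0.4, device offset
−0.35, devices balanced within groups.

## Bayesian multilevel models

All regressions are Gaussian with the study's priors: Student-t(3, 0, 3) on
population coefficients of the smoothness models (t(3, 0, 1) for the
pre-intervention clinical regressions), half-t(3) left-bounded at zero on
SDs, and LKJ(η = 2) on the correlation matrix of correlated varying
coefficients. The intercept prior (unstated) defaults to a t(3, 0, scale)
matching the slopes. The model ladder `smoothness_model(1:7)` reproduces
the fitted sequence: group only; group × session; varying session slopes;
`pre.z` with varying loading; capture device; and the two post-hoc
interaction extensions (group × device, baseline × device), which were
described only in prose and are implemented as additive extensions of
model #5.

No probabilistic-programming engine is involved: the sampler is a blocked
Gibbs scheme written for exactly this model family.

* Population coefficients use the scale-mixture representation of the
  Student-t (per-coefficient inverse-gamma mixing variances) and are drawn
  jointly from their Gaussian full conditional **with the random effects
  integrated out** (per-patient Woodbury blocks of the marginal covariance);
  collapsing removes the slow random walk between the intercept and the mean
  of the varying intercepts.
* Varying coefficients are conjugate Gaussian draws per patient.
* The residual SD uses the Huang–Wand inverse-gamma mixture of the half-t,
  which keeps it conjugate; so does a single varying-intercept SD.
* With two or more varying terms, the SDs and the free correlations are
  updated by adaptive random-walk Metropolis against the *marginal*
  likelihood (again the Woodbury blocks), with the LKJ density as prior;
  marginalization removes the funnel between the effects and their scales.
  Proposals adapt toward 44% / 30% acceptance during warm-up only.

Defaults are 4 chains × 2,000 iterations with half warm-up; convergence is
gated at split-R̂ < 1.01 and reported per parameter together with an
autocorrelation-based effective sample size. A failed gate returns the fit
with `converged = FALSE` and a warning rather than an error, so pipelines
can log and continue. Identical data and seed reproduce summaries exactly.
The contract is distributional, not draw-for-draw: recovery, shrinkage,
prior-predictive and interval-calibration tests (85–95% empirical coverage
of the 90% intervals over null simulations) enforce it, and fits are
cross-checked against `lme4` point estimates during development.

PSIS-LOO is computed from the pointwise log-likelihood (conditional on the
varying effects, the default conditional formulation): per observation the
importance ratios' largest 20% are replaced by order statistics of a
generalized Pareto distribution fitted with the Zhang–Stephens profile
quasi-likelihood estimator (shape regularized toward 0.5), truncated at the
raw maximum; the tail shape k is reported per observation and values above
0.7 are flagged. On an n = 8 normal model the approximation sits within 0.3
of the exact answer computed by eight refits — the brute-force oracle in the
test suite. Model comparison reports elpd differences with paired standard
errors from the per-observation contributions.

## EEG–EMG coherence

Preprocessing applies, per channel: linear detrend, 2–80 Hz band-pass, a
1–80 Hz 3rd-order zero-phase Butterworth band-pass, and a 49–51 Hz notch.
The two band-passes are both applied, in that order, because the published
chain lists them sequentially (it is ambiguous whether the first was merely
preliminary; applying both is harmless — re-filtering changes the in-band
signal by < 1% RMS, which is tested). 50 Hz is attenuated far beyond the
40 dB requirement and 18 Hz passes within 5%.

EMG onsets are threshold crossings of a 50 ms moving-average envelope of the
rectified signal (threshold 30–110 μV according to noise level, default
30 μV), with a 3 s refractory lockout and a ≤ 40 ms backtrack to the burst
foot — zero-phase filtering spreads burst energy slightly backwards in time.
Epochs span −1 to +2 s around onsets (unstated in the original; chosen to
cover the movement-related beta burst); an automated peak-to-peak criterion
(150 μV on any EEG channel) substitutes for visual trial inspection, and
every rejection is returned with its reason.

The WPLI uses one Hann taper per epoch and pools the imaginary cross-spectra
of all (trial × frequency-bin) pairs inside 14–20 Hz:
`WPLI = |Σ Im S_xy| / Σ |Im S_xy|`. Pooling, rather than averaging per-bin
WPLI values over the band, matters for the null level: the per-bin estimator
has a positive bias of order 1/√n_trials (≈ 0.1 at 100 trials), while the
pooled estimator's null level is an order of magnitude smaller, matching the
behaviour the tests demand of independent signals. When the total imaginary
energy is negligible relative to the cross-spectral magnitude — zero-lag
identical signals, where volume conduction is the only interaction — the
WPLI is defined as 0. Significance per channel is a two-sided jackknife z
test of the *debiased* (pairwise) estimator, which is centred at zero under
independence; the plain estimator's variance is also jackknifed and
reported.

The cluster test treats trials as the unit of observation. Its per-trial
statistic is the band-pooled normalized imaginary cross-spectrum
`u_t = Σ Im / Σ |Im| ∈ [−1, 1]` — the per-trial analogue of the WPLI's sign
consistency. We initially used jackknife pseudovalues of the WPLI here, but
pseudovalues are mutually correlated within a condition and label
permutation over them measured a type-I error of ~0.10 at nominal 0.05; the
`u_t` are independent across trials, making the permutation exact, and the
measured false-positive rate drops comfortably under the nominal level with
no loss of power on injected coupling. Channels are oriented by the pooled
sign of the imaginary part (label-invariant), so a positive cluster means
stronger phase-locking post. Channel-wise two-sample t statistics are
thresholded two-sided at α = 0.05; a suprathreshold channel enters a cluster
only with ≥ 2 suprathreshold neighbours (single pass — iterating the prune
to a fixed point would dissolve the legitimate three-channel configurations
the rule is meant to admit); connected components are summed, and cluster p
values come from the permutation distribution of the maximum absolute
cluster statistic (1,000 permutations by default).

Adjacency lives on a schematic 2D layout of the 19 standard 10–20 positions
plus Oz; the distance threshold (0.63 of the head radius) was set so the
mean neighbour count is ~4 (within the 3–5 working range) and C3's
neighbours are {F3, P3, T3, Cz}.

The ephys generator writes 200 Hz recordings with 1/f EEG background, a
per-trial random-phase beta burst (0.25–2.25 s after each onset) in the
coupled channels, and an EMG whose burst-windowed beta component mixes the
lagged cortical oscillation (weight = coupling strength) with an
independent-phase one. The default 15 ms cortex-muscle lag keeps the
interaction phase inside one quadrant across 14–20 Hz, so band-pooling adds
coherently. EMG noise amplitudes scale with the design's noise SD, making
the zero-noise limit a clean phase-locked pair with WPLI = 1. What the
generator does **not** emulate: volume conduction between EEG channels,
heteroscedastic muscle artifacts, eye blinks, or realistic hemiparetic
movement variability — passing tests show the estimators behave correctly,
not that the pipeline is robust to every artifact class of real recordings.

## Problem sizes in the test suite

The validation suites run at deliberately scaled sizes chosen as the
smallest that make the statistical contracts sharp: interval calibration
uses 60 null cohorts of 8 patients; cluster type-I uses 200 null subjects
with 24 trials per condition and 500 permutations; group-effect recovery
uses 20 replicate cohorts at the study's size (14 + 14 patients, 15 sessions,
four-scale task) with 2 × 1,200 MCMC iterations; the PSIS-LOO oracle uses
n = 8 with 4,000 draws. Every stochastic test fixes its seeds.

## Known limitations

* The optical dialect cannot express corruption below its noise floor
  (grid step 0 → 1), as discussed above.
* PSIS-LOO at very small n is mildly optimistic relative to exact refits
  (≈ 0.03 per observation here) — inherent to truncated importance
  sampling, and well inside the tested tolerance.
* Models #6 and #7 are our additive reading of a prose description.
* The sampler is specialized to Gaussian outcomes with a single grouping
  factor — exactly the family the analysis needs, and nothing more.
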