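# sonirehab

Analysis pipeline for studies of **musical sonification in upper-limb stroke
rehabilitation**: patients move their paretic arm inside an instrumented
wooden frame whose vertical axis is mapped to the first six notes of the C
major scale (c′ = 226.6 Hz at the bottom to a′ = 440 Hz at the top), the
left–right axis to timbre, and depth to loudness, so that smooth, accurate
movements literally sound better. The package is written for movement
scientists and neurorehabilitation researchers who want to analyse — or
simulate and power-check — such training data end to end.

It covers four stages, each usable on its own:

1. **Sonification** — deterministic mapping from 3D hand position to
   discrete note events (pitch interval, timbre zone, loudness ramp), with
   hysteresis debouncing, plus JSON-lines and Standard MIDI event writers.
2. **Movement smoothness** — trajectories are resampled, segmented into
   upward/downward strokes, and each stroke scored as
   `MedianLC = median(−ln κ²)`, where
   `κ² = (|v|²|a|² − (v·a)²) / |v|⁶` is the squared geometric curvature of
   the 3D hand path; straighter, smoother paths score higher.
3. **Group modelling** — Bayesian multilevel regressions of z-scored
   smoothness on group, session, baseline smoothness and capture device
   (`MedianLC ~ Group.c × Session.c + pre.z + MoCap.c +
   (Session.c + pre.z | IDanon)` and its simpler ladder), with Student-t(3)
   priors on coefficients, half-t(3) priors on SDs and an LKJ(2) prior on
   varying-coefficient correlations, fitted by a blocked Gibbs sampler and
   compared by PSIS-LOO expected log predictive density.
4. **Cortico-muscular coherence** — EMG onset detection, the
   detrend/band-pass/notch filter chain, low-beta (14–20 Hz) EEG–EMG
   weighted phase lag index `WPLI = |Σ Im S_xy| / Σ |Im S_xy|` per 10–20
   channel, and a cluster-based permutation test of post- vs. pre-therapy
   coupling maps (min-2-neighbour rule, trials as unit of observation).

Because raw patient data of such studies are rarely shareable, the package
ships first-class synthetic-data generators with known ground truth —
quasi-minimum-jerk strokes with controllable sub-movement corruption and
two motion-capture noise dialects, clinical score tables, and EEG+EMG with
tunable lateralized beta coupling — and every estimator is validated
against them.

## Worked example

```r
library(sonirehab)

# the printed pitch endpoints of the training frame
map_pitch(c(2, 50))
#>   pitch_index frequency in_frame
#> 1           1     226.6     TRUE
#> 2           6     440.0     TRUE

# a clean up-down scale sonifies into the task's 11-note sequence
tr <- gen_trajectory(task_spec(repetitions = 1), corruption = 0,
                     seed = 1, noise_sd = 0)
sonify(resample_trajectory(tr))$pitch_index
#> [1] 1 2 3 4 5 6 5 4 3 2 1

# smoothness of an analytic fixture: a 10 cm constant-speed circle has
# kappa^2 = 0.01 cm^-2 everywhere, so MedianLC = -ln(0.01)
th <- seq(0, 2 * pi, length.out = 400)
circle <- data.frame(t_s = seq_along(th) / 60, x_cm = 10 * cos(th),
                     y_cm = 10 * sin(th), z_cm = 0)
stroke_smoothness(circle, smooth_hz = NA)
#> [1] 4.60517

# a corrupted four-scale trial: 8 strokes, lower smoothness than clean
rough <- gen_trajectory(task_spec(), corruption = 3, seed = 7)
strokes <- segment_strokes(resample_trajectory(rough))
length(strokes); median(sapply(strokes, stroke_smoothness))
#> [1] 8
#> [1] 7.32
```

`4.60517` is the analytic `2 ln r` of the circle fixture; the corrupted
trial's `7.32` sits below the clean-movement baseline (~8.3 for the
inertial dialect), which is exactly the gradient the group models estimate
from cohort records.

The numbered scripts under `analysis/` run the full study-shaped workflow —
`01_simulate.R` (cohort, clinical table, pre/post ephys), `02_sonify.R`,
`03_smoothness.R`, `04_group_models.R` (ladder #1–#5 plus PSIS-LOO
comparison), `05_coherence.R` (WPLI maps and the cluster test) — writing
tables under `results/`. `run_pipeline()` does the same in one call with a
single config object and a provenance-stamped manifest.

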