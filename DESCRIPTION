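Package: sonirehab
Title: Movement Sonification Analysis for Upper-Limb Stroke Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studies of musical sonification of arm
    movements in stroke rehabilitation. Simulates quasi-minimum-jerk vertical
    hand trajectories with controllable sub-movement corruption and two
    motion-capture noise dialects; maps 3D hand positions within a training
    frame to discrete musical events (pitch, timbre, loudness); scores
    movement smoothness as the per-stroke median of the negative log squared
    3D path curvature; fits Bayesian multilevel regressions of smoothness on
    group, session, baseline smoothness and capture device with Student-t and
    LKJ priors via a blocked Gibbs sampler, compared by Pareto-smoothed
    importance-sampling leave-one-out cross-validation; and quantifies
    cortico-muscular coupling as the low-beta weighted phase lag index
    between EEG and EMG with cluster-based permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
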