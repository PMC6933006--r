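# shared fixtures, all built in code

# constant-speed circle in the x-y plane; radius in cm
circle_stroke <- function(radius = 10, n = 400, rate = 60, revs = 1) {
  th <- seq(0, revs * 2 * pi, length.out = n)
  st <- data.frame(t_s = seq_len(n) / rate,
                   x_cm = radius * cos(th), y_cm = radius * sin(th),
                   z_cm = 0)
  attr(st, "rate_hz") <- rate
  st
}

# numeric multilevel records with known effects, bypassing the trajectory
# machinery (for sampler-focused tests)
make_records <- function(J = 10, nper = 6, group_effect = 0, patient_sd = 0.5,
                         pre_loading = 0, sigma = 1, seed = 1) {
  set.seed(seed)
  id <- rep(sprintf("P%02d", seq_len(J)), each = nper)
  gi <- as.integer(factor(id))
  gr <- rep(c(-0.5, 0.5), length.out = J)
  prez <- as.numeric(scale(rnorm(J)))
  sess <- rep(seq_len(nper) - (nper + 1) / 2, J)
  a <- rnorm(J, 0, patient_sd)
  y <- group_effect * gr[gi] + pre_loading * prez[gi] + a[gi] +
    rnorm(J * nper, 0, sigma)
  data.frame(MedianLC = y, Group.c = gr[gi], Session.c = sess,
             pre.z = prez[gi], MoCap.c = rep(c(-0.5, 0.5), length.out = J)[gi],
             IDanon = id)
}

# small trial sets for coherence tests
make_trials <- function(coupling = 0, channels = "C3", n_trials = 24,
                        seed = 1, noise_sd = 10, beta_amp = 5, emg_beta = 30) {
  d <- coupling_design(coupling_strength = coupling,
                       coupled_channels = channels,
                       n_trials = n_trials, noise_sd = noise_sd, seed = seed)
  rec <- preprocess(gen_ephys(d, beta_amp_uv = beta_amp,
                              emg_beta_amp_uv = emg_beta))
  epoch_recording(rec, reject_uvpp = Inf)
}
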