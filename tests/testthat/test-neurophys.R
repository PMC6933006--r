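make_rec <- function(eeg, emg, rate = 200) {
  structure(list(eeg = eeg, emg = emg, rate = rate,
                 events = integer(0), channels = rownames(eeg)),
            class = "ephys_recording")
}

test_that("the filter chain notches line noise and preserves the beta band", {
  t <- (1:4000) / 200
  rec <- make_rec(matrix(sin(2 * pi * 50 * t), 1, 4000,
                         dimnames = list("Cz", NULL)),
                  matrix(sin(2 * pi * 18 * t), 1, 4000,
                         dimnames = list("DELT", NULL)))
  out <- preprocess(rec)
  mid <- 1000:3000
  att50 <- -20 * log10(sd(out$eeg[1, mid]) / sd(rec$eeg[1, mid]))
  expect_gte(att50, 40)
  gain18 <- sd(out$emg[1, mid]) / sd(rec$emg[1, mid])
  expect_lt(abs(gain18 - 1), 0.05)
  # linear trends are removed
  tr <- make_rec(matrix(5 + 3 * t, 1, 4000, dimnames = list("Cz", NULL)),
                 matrix(0, 1, 4000, dimnames = list("DELT", NULL)))
  dt <- preprocess(tr)
  expect_lt(abs(mean(dt$eeg[1, mid])), 0.05)
  expect_lt(abs(coef(lm(dt$eeg[1, mid] ~ mid))[2]), 1e-3)
  # sampling too slow for the 80 Hz corner
  slow <- make_rec(matrix(0, 1, 100, dimnames = list("Cz", NULL)),
                   matrix(0, 1, 100, dimnames = list("DELT", NULL)),
                   rate = 120)
  expect_error(preprocess(slow), "Nyquist")
})

test_that("re-filtering changes the in-band signal by less than 1% RMS", {
  t <- (1:6000) / 200
  sig <- sin(2 * pi * 18 * t) + 0.5 * sin(2 * pi * 9 * t)
  rec <- make_rec(matrix(sig, 1, 6000, dimnames = list("Cz", NULL)),
                  matrix(sig, 1, 6000, dimnames = list("DELT", NULL)))
  once <- preprocess(rec)
  twice <- preprocess(once)
  mid <- 1500:4500
  rel <- sqrt(mean((twice$eeg[1, mid] - once$eeg[1, mid])^2)) /
    sqrt(mean(once$eeg[1, mid]^2))
  expect_lt(rel, 0.01)
})

test_that("EMG onsets are found at burst starts with a refractory lockout", {
  d <- coupling_design(coupling_strength = 0, n_trials = 20, seed = 3)
  rec <- gen_ephys(d)
  on <- detect_onsets(preprocess(rec))
  expect_length(on, 20)
  expect_lt(max(abs(on - rec$events)) / 200, 0.05)
  expect_length(detect_onsets(preprocess(rec), threshold_uv = 1e7), 0)
  # two bursts 1 s apart collapse under a 3 s refractory period
  t <- (1:2000) / 200
  emg <- numeric(2000)
  emg[301:400] <- 100
  emg[501:600] <- 100
  expect_length(detect_onsets(emg, threshold_uv = 50, rate = 200), 1)
  expect_error(detect_onsets(emg, rate = 200, refractory_s = 0), "positive")
  expect_error(detect_onsets(emg, threshold_uv = 50), "rate")
})

test_that("epoching drops edge events and rejects artifact trials exactly", {
  d <- coupling_design(coupling_strength = 0, n_trials = 12, seed = 4)
  rec <- preprocess(gen_ephys(d))
  tr <- epoch_recording(rec, reject_uvpp = Inf)
  expect_equal(dim(tr$epochs)[1], 12)
  expect_equal(dim(tr$epochs)[3], 3 * 200)
  # events too close to the record edges are dropped with a reason
  ev <- c(50, rec$events, ncol(rec$eeg) - 50)
  tr2 <- epoch_recording(rec, events = ev, reject_uvpp = Inf)
  expect_equal(dim(tr2$epochs)[1], 12)
  expect_equal(nrow(tr2$rejected), 2)
  expect_match(tr2$rejected$reason[1], "outside")
  # amplitude artifacts injected into 3 known trials are exactly rejected
  rec3 <- rec
  for (k in c(2, 5, 9)) {
    at <- rec3$events[k] + 100
    rec3$eeg["Cz", at:(at + 10)] <- 500
  }
  tr3 <- epoch_recording(rec3, reject_uvpp = 150)
  expect_equal(tr3$rejected$trial, c(2, 5, 9))
  expect_equal(dim(tr3$epochs)[1], 9)
})

test_that("WPLI hits its analytic limits", {
  # perfect lagged coupling, no noise -> 1 at the coupled channel
  tr1 <- make_trials(coupling = 1, channels = "C3", n_trials = 12,
                     noise_sd = 1e-9, seed = 5)
  w1 <- wpli(tr1)
  expect_equal(w1$wpli[w1$channel == "C3"], 1, tolerance = 1e-6)
  expect_true(w1$significant[w1$channel == "C3"])
  # zero-lag identical signals -> defined as 0 by convention
  set.seed(6)
  x <- rnorm(12 * 21 * 600)
  ep <- array(rep(rnorm(12 * 600), each = 21), c(21, 12, 600))
  ep <- aperm(ep, c(2, 1, 3))
  trials <- structure(list(epochs = ep, rate = 200, window = c(-1, 2),
                           eeg_channels = montage_1020()$channel,
                           emg_channels = "DELT"), class = "trial_set")
  dimnames(trials$epochs) <- list(NULL,
                                  c(montage_1020()$channel[1:20], "DELT")[1:21],
                                  NULL)
  # make every channel identical to the EMG channel
  for (ch in seq_len(20)) trials$epochs[, ch, ] <- trials$epochs[, 21, ]
  trials$eeg_channels <- dimnames(trials$epochs)[[2]][1:20]
  w0 <- wpli(trials)
  expect_true(all(w0$wpli == 0))
  expect_false(any(w0$significant))
})

test_that("WPLI is bounded, amplitude-invariant, and polarity-invariant", {
  tr <- make_trials(coupling = 0.6, channels = "C3", n_trials = 16, seed = 7)
  w <- wpli(tr)
  expect_true(all(w$wpli >= 0 & w$wpli <= 1))
  # rescaling any channel leaves WPLI unchanged
  tr2 <- tr; tr2$epochs[, "C3", ] <- 7.3 * tr2$epochs[, "C3", ]
  expect_equal(wpli(tr2)$wpli, w$wpli, tolerance = 1e-9)
  # flipping EMG polarity leaves WPLI unchanged
  tr3 <- tr; tr3$epochs[, "DELT", ] <- -tr3$epochs[, "DELT", ]
  expect_equal(wpli(tr3)$wpli, w$wpli, tolerance = 1e-12)
  expect_error(wpli(tr, band = c(90, 95)), "passband")
  small <- tr; small$epochs <- small$epochs[1:5, , , drop = FALSE]
  expect_error(wpli(small), "at least 10")
})

test_that("independent noise keeps WPLI low and unflagged", {
  tr <- make_trials(coupling = 0, channels = "C3", n_trials = 100, seed = 8,
                    beta_amp = 0, emg_beta = 0)
  w <- wpli(tr)
  expect_lt(max(w$wpli), 0.1)
  expect_gte(sum(!w$significant), 18)
})

test_that("the 10-20 adjacency is symmetric with sane neighbourhoods", {
  adj <- neighbors_1020()
  expect_true(isSymmetric(adj))
  expect_true(all(diag(adj) == FALSE))
  mn <- mean(rowSums(adj))
  expect_gte(mn, 3); expect_lte(mn, 5)
  c3 <- colnames(adj)[adj["C3", ]]
  expect_true(all(c("F3", "P3", "T3", "Cz") %in% c3))
  expect_error(neighbors_1020(channels = c("C3", "QQ1")), "unknown")
})

test_that("cluster permutation finds injected coupling and respects the
          neighbour rule", {
  pre <- make_trials(coupling = 0, channels = "C3", n_trials = 30, seed = 20)
  post <- make_trials(coupling = 0.8, channels = c("C3", "F3", "P3"),
                      n_trials = 30, seed = 21)
  res <- cluster_permutation(pre, post, n_perm = 400, seed = 2)
  pos <- Filter(function(cl) cl$sign == "positive", res$clusters)
  expect_gte(length(pos), 1)
  hit <- Filter(function(cl) "C3" %in% cl$channels, pos)
  expect_gte(length(hit), 1)
  expect_lt(hit[[1]]$p, 0.05)
  # an isolated suprathreshold channel cannot form a cluster: inject only at
  # Oz, whose neighbours (O1, O2) stay subthreshold
  post2 <- make_trials(coupling = 0.9, channels = "Oz", n_trials = 30,
                       seed = 22)
  res2 <- cluster_permutation(pre, post2, n_perm = 300, seed = 3)
  oz <- Filter(function(cl) "Oz" %in% cl$channels, res2$clusters)
  expect_length(oz, 0)
  # mismatched channel sets are refused
  bad <- post; bad$eeg_channels <- rev(bad$eeg_channels)
  expect_error(cluster_permutation(pre, bad), "different channels")
  expect_error(cluster_permutation(pre, post, n_perm = 50), "200")
})

test_that("the permutation rank of a null statistic is roughly uniform", {
  # under exchangeable labels the observed max-cluster statistic should not
  # sit systematically in the tail of its permutation distribution
  set.seed(30)
  pvals <- replicate(12, {
    s <- sample.int(1e6, 2)
    pre <- make_trials(coupling = 0, n_trials = 16, seed = s[1])
    post <- make_trials(coupling = 0, n_trials = 16, seed = s[2])
    res <- cluster_permutation(pre, post, n_perm = 200, seed = s[1])
    if (length(res$clusters))
      min(vapply(res$clusters, function(cl) cl$p, 0)) else 1
  })
  expect_gte(sum(pvals > 0.2), 6)   # most null runs are clearly insignificant
})
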