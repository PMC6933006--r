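test_that("resampling is the identity on already-uniform input", {
  t <- (0:120) / 60
  tr <- data.frame(t_s = t, x_cm = sin(t), y_cm = 2 * t, z_cm = cos(t),
                   valid_flag = 1L)
  out <- resample_trajectory(tr, rate_hz = 60)
  expect_equal(out$y_cm, tr$y_cm, tolerance = 1e-9)
  expect_equal(out$t_s, tr$t_s, tolerance = 1e-9)
})

test_that("jittered samples of a linear ramp interpolate exactly", {
  set.seed(1)
  t <- sort(runif(200, 0, 5))
  tr <- data.frame(t_s = t, x_cm = 3 * t + 1, y_cm = -2 * t, z_cm = 0 * t,
                   valid_flag = 1L)
  out <- resample_trajectory(tr, rate_hz = 60)
  expect_equal(out$x_cm, 3 * out$t_s + 1, tolerance = 1e-9)
  expect_equal(out$y_cm, -2 * out$t_s, tolerance = 1e-9)
})

test_that("long dropout gaps are flagged and excluded, short ones bridged", {
  t <- (0:300) / 60
  tr <- data.frame(t_s = t, x_cm = 0, y_cm = t, z_cm = 0, valid_flag = 1L)
  tr$valid_flag[t > 2 & t < 2.5] <- 0L   # 0.5 s gap
  tr$valid_flag[100:101] <- 0L           # ~33 ms gap
  out <- resample_trajectory(tr, rate_hz = 60)
  gap_samples <- out$valid_flag[out$t_s > 2 & out$t_s < 2.5]
  expect_true(all(gap_samples == 0))
  expect_equal(sum(out$valid_flag == 0), sum(out$t_s > 2 & out$t_s < 2.5))
  expect_error(resample_trajectory(tr[tr$valid_flag == 9, ]), "valid")
})

test_that("a four-scale trajectory segments into 8 alternating strokes", {
  tr <- gen_trajectory(task_spec(), corruption = 0, seed = 2)
  st <- segment_strokes(resample_trajectory(tr))
  expect_length(st, 8)
  dirs <- vapply(st, function(s) attr(s, "direction"), "")
  expect_equal(dirs, rep(c("up", "down"), 4))
})

test_that("flat and sub-threshold trajectories yield no strokes", {
  t <- (0:600) / 60
  flat <- data.frame(t_s = t, x_cm = 0, y_cm = 20 + 0.01 * sin(t),
                     z_cm = 0, valid_flag = 1L)
  attr(flat, "rate_hz") <- 60
  expect_length(segment_strokes(flat), 0)
  # wiggles below the amplitude threshold between genuine strokes
  y <- c(min_jerk(seq(0, 1, length.out = 120), 5, 45),
         45 + 2 * sin(seq(0, 6 * pi, length.out = 60)),
         min_jerk(seq(0, 1, length.out = 120), 45, 5))
  tr <- data.frame(t_s = seq_along(y) / 60, x_cm = 0, y_cm = y, z_cm = 0,
                   valid_flag = 1L)
  attr(tr, "rate_hz") <- 60
  st <- segment_strokes(tr)
  expect_length(st, 2)
  expect_equal(vapply(st, function(s) attr(s, "direction"), ""),
               c("up", "down"))
})

test_that("squared curvature of a constant-speed circle is 1/r^2", {
  st <- circle_stroke(radius = 10)
  cs <- curvature_sq(st, smooth_hz = NA)
  interior <- cs$kappa_sq[5:(length(cs$kappa_sq) - 5)]
  expect_true(all(abs(interior - 0.01) / 0.01 < 0.01))
  # and the smoothness statistic is -ln(1/r^2) = 2 ln r
  expect_equal(as.numeric(stroke_smoothness(st, smooth_hz = NA)),
               -log(0.01), tolerance = 1e-4)
})

test_that("straight-line motion clamps to the curvature floor", {
  t <- (0:199) / 60
  st <- data.frame(t_s = t, x_cm = 5 * t, y_cm = 3 * t, z_cm = 0)
  attr(st, "rate_hz") <- 60
  cs <- curvature_sq(st, smooth_hz = NA)
  expect_equal(cs$clamped_fraction, 1)
  expect_true(all(cs$kappa_sq == 1e-12))
  sm <- stroke_smoothness(st, smooth_hz = NA)
  expect_equal(as.numeric(sm), -log(1e-12), tolerance = 1e-6)
  expect_equal(attr(sm, "clamped_fraction"), 1)
})

test_that("finite-difference curvature matches a 10x-oversampled oracle", {
  # smooth fixture: minimum-jerk rise with a lateral bow
  make <- function(rate) {
    tau <- seq(0, 1, length.out = round(2 * rate))
    data.frame(t_s = tau * 2, x_cm = 0,
               y_cm = min_jerk(tau, 5, 45),
               z_cm = 1.5 * sin(pi * tau)^2)
  }
  st <- make(60); attr(st, "rate_hz") <- 60
  ov <- make(600); attr(ov, "rate_hz") <- 600
  k1 <- curvature_sq(st, smooth_hz = NA)$kappa_sq
  k2 <- curvature_sq(ov, smooth_hz = NA)$kappa_sq
  # compare interior samples at matching times
  idx1 <- 10:(length(k1) - 10)
  idx2 <- round(seq(1, length(k2), length.out = length(k1)))[idx1]
  rel <- abs(k1[idx1] - k2[idx2]) / k2[idx2]
  expect_lt(max(rel), 0.02)
})

test_that("curvature is geometric: scale and speed behave as expected", {
  st <- circle_stroke(radius = 10)
  s3 <- circle_stroke(radius = 30)
  sm1 <- as.numeric(stroke_smoothness(st, smooth_hz = NA))
  sm3 <- as.numeric(stroke_smoothness(s3, smooth_hz = NA))
  expect_equal(sm3 - sm1, 2 * log(3), tolerance = 1e-3)
  # doubling traversal speed leaves kappa^2 unchanged under p = 3
  fast <- circle_stroke(radius = 10, n = 400, rate = 120)
  expect_equal(as.numeric(stroke_smoothness(fast, smooth_hz = NA)), sm1,
               tolerance = 1e-3)
  # the printed p = 1 variant is speed-dependent by construction
  p1_slow <- median(curvature_sq(st, p = 1, smooth_hz = NA)$kappa_sq)
  p1_fast <- median(curvature_sq(fast, p = 1, smooth_hz = NA)$kappa_sq)
  expect_gt(p1_fast / p1_slow, 2)
})

test_that("stroke segmentation recovers >= 95% of true strokes on a cohort", {
  hits <- 0; total <- 0
  for (k in 1:10) {
    tr <- gen_trajectory(task_spec(), corruption = 1.5,
                         dialect = if (k %% 2) "inertial" else "optical",
                         seed = 700 + k)
    st <- segment_strokes(resample_trajectory(tr))
    total <- total + 8
    dirs <- vapply(st, function(s) attr(s, "direction"), "")
    hits <- hits + min(sum(dirs == "up"), 4) + min(sum(dirs == "down"), 4)
  }
  expect_gte(hits / total, 0.95)
})

test_that("build_records assembles covariates with the stated conventions", {
  sets <- list(list(strokes = rnorm(8, 5), meta = list(
    patient = "P01", group = "treatment", session = 1, device = "inertial")))
  rec <- build_records(sets, z_outcome = FALSE)
  expect_equal(nrow(rec), 8)
  expect_true(all(rec$Group.c == 0.5) && all(rec$MoCap.c == 0.5))
  expect_equal(names(rec)[1:6],
               c("IDanon", "Group.c", "Session.c", "pre.z", "MoCap.c",
                 "MedianLC"))

  # two-device cohort with baseline + 2 modelled sessions
  sets2 <- list()
  for (p in 1:4) for (s in 0:2) {
    sets2[[length(sets2) + 1]] <- list(
      strokes = rnorm(4, mean = 5 + p / 2),
      meta = list(patient = sprintf("P%02d", p),
                  group = if (p <= 2) "treatment" else "control",
                  session = s,
                  device = if (p %% 2) "inertial" else "optical"))
  }
  rec2 <- build_records(sets2)
  expect_setequal(unique(rec2$MoCap.c), c(-0.5, 0.5))
  expect_false(0 %in% rec2$session)        # baseline excluded from records
  expect_equal(mean(rec2$MedianLC), 0, tolerance = 1e-9)
  expect_equal(sd(rec2$MedianLC), 1, tolerance = 1e-9)
  # pre.z standardized across patients, constant within patient
  per_pat <- vapply(split(rec2$pre.z, rec2$IDanon), function(v)
    diff(range(v)), 0)
  expect_true(all(per_pat == 0))
  # incomplete metadata is dropped with a log entry, not an error
  sets3 <- c(sets2, list(list(strokes = rnorm(3),
                              meta = list(patient = "P09", group = NA,
                                          session = 1, device = "optical"))))
  rec3 <- build_records(sets3)
  expect_length(attr(rec3, "dropped"), 1)
  expect_false("P09" %in% rec3$IDanon)
})
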