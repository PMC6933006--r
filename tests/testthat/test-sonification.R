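test_that("pitch mapping hits the printed endpoints and boundary convention", {
  p <- map_pitch(c(2, 50, 51, 25.5))
  expect_equal(p$pitch_index, c(1L, 6L, 6L, 4L))
  expect_equal(p$frequency[1], 226.6)
  expect_equal(p$frequency[2], 440)
  expect_equal(p$frequency[3], 440)  # top boundary closed into interval 6

  out <- map_pitch(c(-1, 52))
  expect_false(any(out$in_frame))
  expect_true(all(is.na(out$frequency)))
})

test_that("every in-frame position maps to exactly one (field, pitch, timbre)", {
  set.seed(42)
  x <- runif(200, 0, 51); y <- runif(200, 0, 51); z <- runif(200, 0, 51)
  p <- map_pitch(y); l <- locate(x, z)
  expect_true(all(p$in_frame) && all(l$in_frame))
  expect_true(all(p$pitch_index %in% 1:6))
  expect_true(all(l$field_index %in% 1:9))
  expect_true(all(l$timbre_zone %in% c("clarinet", "saxophone", "bowed")))
  # frequency monotone in pitch index for any increasing tuning table
  tun <- sort(runif(6, 100, 1000))
  p2 <- map_pitch(y, tuning = tun)
  ord <- order(p2$pitch_index)
  expect_true(all(diff(p2$frequency[ord]) >= 0))
})

test_that("board location: timbre thirds, loudness ramp, field numbering", {
  expect_equal(locate(5, 25)$timbre_zone, "clarinet")
  expect_equal(locate(25.5, 25)$timbre_zone, "saxophone")
  expect_equal(locate(45, 25)$timbre_zone, "bowed")
  expect_equal(locate(10, 0)$loudness_db, 0)      # proximal = loudest
  expect_equal(locate(10, 51)$loudness_db, -20)
  expect_lt(locate(10, 30)$loudness_db, locate(10, 10)$loudness_db)
  expect_equal(locate(25.5, 25.5)$field_index, 5L)  # centre of 3x3
  expect_equal(locate(5, 5)$field_index, 1L)        # near-left corner
  expect_equal(locate(45, 45)$field_index, 9L)
  expect_true(is.na(locate(-3, 10)$field_index))
})

test_that("slow monotone sweep yields 6 events with ascending frequencies", {
  t <- seq(0, 20, by = 1 / 60)
  tr <- data.frame(t_s = t, x_cm = 25.5, y_cm = 51 * t / 20, z_cm = 25.5,
                   valid_flag = 1L)
  ev <- sonify(tr)
  expect_equal(nrow(ev), 6)
  expect_true(all(diff(ev$frequency) > 0))
  expect_equal(ev$pitch_index, 1:6)
})

test_that("planar sweep passes through all 9 fields", {
  xs <- seq(0.5, 50.5, length.out = 60)
  fields <- unique(unlist(lapply(seq(0.5, 50.5, length.out = 60), function(z)
    locate(xs, rep(z, length(xs)))$field_index)))
  expect_setequal(fields, 1:9)
})

test_that("stationary hand sustains a single event", {
  t <- seq(0, 10, by = 1 / 60)
  tr <- data.frame(t_s = t, x_cm = 10, y_cm = 20, z_cm = 10, valid_flag = 1L)
  ev <- sonify(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$offset_s - ev$onset_s, 10, tolerance = 0.01)
})

test_that("hysteresis debounces boundary jitter into one event", {
  # oscillate within +/- (hys/2)*interval around the 8.5 cm boundary
  hys <- 0.1
  interval <- 51 / 6
  t <- seq(0, 5, by = 1 / 60)
  y <- 8.5 + (hys / 2) * interval * sin(2 * pi * 3 * t) / 2
  tr <- data.frame(t_s = t, x_cm = 25, y_cm = y, z_cm = 25, valid_flag = 1L)
  ev <- sonify(tr, hysteresis_fraction = hys)
  expect_equal(nrow(ev), 1)
  expect_error(sonify(tr, hysteresis_fraction = 0.6), "hysteresis")
})

test_that("task event streams enumerate the scale correctly", {
  sc <- task_spec(repetitions = 1)
  ev <- task_events(sc)
  expect_equal(nrow(ev), 11)               # 6 up + 5 down, top note shared
  expect_equal(ev$pitch_index, c(1:6, 5:1))
  expect_equal(nrow(task_events(task_spec(repetitions = 4))), 44)
  iv <- task_spec(note_sequence = c(1, 6), repetitions = 1)
  expect_equal(nrow(task_events(iv)), 2)
})

test_that("sonifying the ideal task trajectory reproduces the task pitches", {
  sc <- task_spec(repetitions = 1)
  tr <- gen_trajectory(sc, corruption = 0, seed = 1, noise_sd = 0,
                       stroke_duration_s = 4)
  ev <- sonify(resample_trajectory(tr))
  ref <- task_events(sc)
  # the sweep starts inside interval 1 and turns inside interval 6, so the
  # emitted pitch sequence must match the task's ideal sequence
  expect_equal(ev$pitch_index, ref$pitch_index)
})

test_that("empty or out-of-frame trajectories emit no events", {
  expect_equal(nrow(sonify(NULL)), 0)
  tr <- data.frame(t_s = 1:5 / 60, x_cm = -10, y_cm = 20, z_cm = 10,
                   valid_flag = 1L)
  expect_equal(nrow(sonify(tr)), 0)
})
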