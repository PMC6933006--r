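#' Task specification
#'
#' A training task: a board field, an ordered sequence of pitch indices
#' (1..6), and a repetition count. The first task of each training day — four
#' up-and-down legato scales over the first six notes at field 1 — is the
#' default.
#'
#' @param position_field Board field 1..9 where the task is performed.
#' @param note_sequence Ordered pitch indices, each within 1..n intervals.
#'   The default is one up-down scale c'-d'-e'-f'-g'-a' and g'-f'-e'-d'-c'.
#' @param repetitions Number of repetitions (>= 1).
#' @return A `task_spec` object.
#' @export
task_spec <- function(position_field = 1,
                      note_sequence = c(1:6, 5:1),
                      repetitions = 4) {
  if (!is.numeric(position_field) || length(position_field) != 1 ||
      position_field < 1 || position_field > 9) {
    stop("`position_field` must be a single integer in 1..9")
  }
  if (any(note_sequence < 1 | note_sequence > 6)) {
    stop("pitch indices must lie within 1..6")
  }
  if (repetitions < 1) stop("`repetitions` must be >= 1")
  structure(list(position_field = as.integer(position_field),
                 note_sequence = as.integer(note_sequence),
                 repetitions = as.integer(repetitions)),
            class = "task_spec")
}

#' Closed-form minimum-jerk position profile
#'
#' Quintic point-to-point profile `x(tau) = x0 + d*(10 tau^3 - 15 tau^4 +
#' 6 tau^5)` with zero velocity and acceleration at both ends; the standard
#' model of smooth human reaching.
#'
#' @param tau Normalized time in `[0, 1]`.
#' @param x0 Start position.
#' @param x1 End position.
#' @return Positions at `tau`.
#' @export
min_jerk <- function(tau, x0 = 0, x1 = 1) {
  tau <- pmin(pmax(tau, 0), 1)
  x0 + (x1 - x0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Generate a synthetic hand trajectory for a task
#'
#' Collapses monotone runs of the task's note sequence into single legato
#' strokes (an up-down scale is one upward and one downward stroke) and renders
#' each stroke as a minimum-jerk vertical movement between the interval-centre
#' heights of the run's endpoints. A small smooth lateral bow (`lateral_bow_cm`
#' in the z direction, peaking mid-stroke) gives the path the gentle curvature
#' of natural reaching, so the clean trajectory has a finite smoothness
#' baseline. Sub-movement corruption superimposes Gaussian-bell velocity bumps
#' on all three axes: the bump count is Poisson(`corruption`) per stroke and
#' bump amplitude grows with `corruption`; the net displacement of each bump is
#' removed so stroke endpoints are unchanged.
#'
#' Two motion-capture noise dialects are supported:
#' \describe{
#'   \item{inertial}{uniform 60 Hz sampling, low additive position noise
#'     (0.05 cm SD) — an IMU-based tracker.}
#'   \item{optical}{jittered sample times, higher position noise (0.08 cm SD)
#'     and occasional dropouts of 1–3 consecutive samples, marked with
#'     `valid_flag = 0` rather than deleted — an optical tracker.}
#' }
#'
#' @param task A [task_spec()].
#' @param corruption Non-negative sub-movement corruption level; 0 gives a
#'   clean quasi-minimum-jerk movement.
#' @param dialect `"inertial"` or `"optical"`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param geometry A [frame_geometry()].
#' @param stroke_duration_s Duration of one stroke in seconds.
#' @param rate_hz Nominal sampling rate.
#' @param lateral_bow_cm Peak lateral (z) bow of the clean stroke path.
#' @param noise_sd Measurement-noise SD in cm; `NULL` uses the dialect's
#'   value (0.05 inertial, 0.08 optical). Set 0 for a noise-free trajectory.
#' @return A data.frame of class `trajectory` with columns `t_s`, `x_cm`,
#'   `y_cm`, `z_cm`, `valid_flag` and attributes `rate_hz`, `dialect`.
#' @export
gen_trajectory <- function(task = task_spec(), corruption = 0,
                           dialect = c("inertial", "optical"), seed = 1,
                           geometry = frame_geometry(),
                           stroke_duration_s = 2, rate_hz = 60,
                           lateral_bow_cm = 1.5, noise_sd = NULL) {
  dialect <- match.arg(dialect)
  if (!is.numeric(corruption) || corruption < 0) {
    stop("`corruption` must be a non-negative real")
  }
  set.seed(as.integer(seed))

  # monotone runs of the note sequence -> legato strokes
  full_seq <- rep(list(task$note_sequence), task$repetitions)
  strokes <- list()
  for (rep_seq in full_seq) {
    runs <- monotone_runs(rep_seq)
    strokes <- c(strokes, runs)
  }

  fl <- field_center(task$position_field, geometry)
  n_per <- max(round(stroke_duration_s * rate_hz), 10)
  dt <- stroke_duration_s / n_per

  t_all <- c(); x_all <- c(); y_all <- c(); z_all <- c()
  t0 <- 0
  for (s in strokes) {
    h0 <- interval_center(s[1], geometry)
    h1 <- interval_center(s[2], geometry)
    tau <- seq(0, 1, length.out = n_per + 1)[-1]  # avoid duplicating joints
    tt <- t0 + tau * stroke_duration_s
    y <- min_jerk(tau, h0, h1)
    # lateral bow: smooth arc peaking mid-stroke, zero at endpoints
    z <- fl["z"] + lateral_bow_cm * sin(pi * tau)^2
    x <- rep(fl["x"], length(tau))
    if (corruption > 0) {
      bump <- submovement_bumps(tau, stroke_duration_s, corruption)
      y <- y + bump$y
      x <- x + bump$x
      z <- z + bump$z
    }
    t_all <- c(t_all, tt); x_all <- c(x_all, x)
    y_all <- c(y_all, y); z_all <- c(z_all, z)
    t0 <- t0 + stroke_duration_s
  }

  n <- length(t_all)
  valid <- rep(1L, n)
  if (dialect == "inertial") {
    if (is.null(noise_sd)) noise_sd <- 0.05
  } else {
    if (is.null(noise_sd)) noise_sd <- 0.08
    t_all <- t_all + stats::runif(n, -0.2, 0.2) / rate_hz  # timing jitter
    t_all <- cummax(t_all)                                  # keep monotone
    # occasional dropouts: ~0.3 events/s of 1-3 samples, flagged not deleted
    n_drop <- stats::rpois(1, 0.3 * max(t_all))
    if (n_drop > 0) {
      starts <- sample.int(n, n_drop)
      lens <- sample(1:3, n_drop, replace = TRUE)
      for (k in seq_len(n_drop)) {
        idx <- starts[k]:min(starts[k] + lens[k] - 1L, n)
        valid[idx] <- 0L
      }
    }
  }
  x_all <- x_all + stats::rnorm(n, 0, noise_sd)
  y_all <- y_all + stats::rnorm(n, 0, noise_sd)
  z_all <- z_all + stats::rnorm(n, 0, noise_sd)

  out <- data.frame(t_s = t_all, x_cm = unname(x_all), y_cm = y_all,
                    z_cm = unname(z_all), valid_flag = valid)
  rownames(out) <- NULL
  attr(out, "rate_hz") <- rate_hz
  attr(out, "dialect") <- dialect
  class(out) <- c("trajectory", class(out))
  out
}

# split a note sequence into monotone runs, returned as (from, to) pairs
monotone_runs <- function(seq) {
  seq <- seq[c(TRUE, diff(seq) != 0)]
  if (length(seq) < 2) return(list())
  dirs <- sign(diff(seq))
  brk <- which(diff(dirs) != 0)
  bounds <- c(1, brk + 1, length(seq))
  runs <- list()
  for (i in seq_len(length(bounds) - 1)) {
    runs[[i]] <- c(seq[bounds[i]], seq[bounds[i + 1]])
  }
  runs
}

# Gaussian-bell velocity bumps integrated into displacement; endpoint-neutral.
# Count ~ Poisson(corruption); amplitude grows with corruption. Returns
# displacement perturbations for the three axes.
submovement_bumps <- function(tau, duration_s, corruption) {
  out <- list(x = 0, y = 0, z = 0)
  amp0 <- 0.4 * corruption  # cm of peak displacement per bump
  for (axis in names(out)) {
    n_b <- stats::rpois(1, corruption)
    d <- numeric(length(tau))
    if (n_b > 0) {
      centers <- stats::runif(n_b, 0.15, 0.85)
      widths <- stats::runif(n_b, 0.06, 0.15)
      amps <- amp0 * stats::runif(n_b, 0.5, 1) * sample(c(-1, 1), n_b, TRUE)
      for (k in seq_len(n_b)) {
        # compactly supported bell: negligible (< 1e-3) at the endpoints,
        # so stroke endpoints are unchanged
        g <- exp(-(tau - centers[k])^2 / (2 * widths[k]^2))
        d <- d + amps[k] * g
      }
    }
    out[[axis]] <- d
  }
  # vertical bumps slightly stronger: arrests/overshoots act along the movement
  out$y <- out$y * 1.5
  out
}
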