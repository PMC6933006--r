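#' Resample a trajectory onto a uniform time grid
#'
#' Linear interpolation of the valid samples onto a uniform grid at `rate_hz`.
#' Dropout gaps longer than `max_gap_s` are not bridged: grid samples falling
#' inside such a gap are flagged invalid (`valid_flag = 0`) and later excluded
#' from strokes. Shorter gaps (e.g. 1–3-sample optical dropouts) are
#' interpolated across.
#'
#' @param trajectory A trajectory data.frame (`t_s`, `x_cm`, `y_cm`, `z_cm`,
#'   optional `valid_flag`).
#' @param rate_hz Target uniform sampling rate.
#' @param max_gap_s Longest gap (seconds) that may be interpolated across.
#' @return A uniform `trajectory` data.frame.
#' @export
resample_trajectory <- function(trajectory, rate_hz = 60, max_gap_s = 0.25) {
  if (is.null(trajectory$valid_flag)) trajectory$valid_flag <- 1L
  keep <- trajectory$valid_flag > 0 &
    is.finite(trajectory$t_s) & is.finite(trajectory$y_cm)
  tr <- trajectory[keep, , drop = FALSE]
  if (nrow(tr) < 2) stop("trajectory has fewer than 2 valid samples")
  tr <- tr[order(tr$t_s), , drop = FALSE]
  tr <- tr[c(TRUE, diff(tr$t_s) > 0), , drop = FALSE]  # drop duplicate stamps

  grid <- seq(tr$t_s[1], tr$t_s[nrow(tr)], by = 1 / rate_hz)
  out <- data.frame(
    t_s = grid,
    x_cm = stats::approx(tr$t_s, tr$x_cm, grid)$y,
    y_cm = stats::approx(tr$t_s, tr$y_cm, grid)$y,
    z_cm = stats::approx(tr$t_s, tr$z_cm, grid)$y,
    valid_flag = 1L
  )
  # flag grid samples that fall inside long source gaps
  gaps <- which(diff(tr$t_s) > max_gap_s)
  for (g in gaps) {
    bad <- out$t_s > tr$t_s[g] & out$t_s < tr$t_s[g + 1]
    out$valid_flag[bad] <- 0L
  }
  attr(out, "rate_hz") <- rate_hz
  attr(out, "dialect") <- attr(trajectory, "dialect")
  class(out) <- c("trajectory", class(out))
  out
}

#' Segment a trajectory into upward and downward strokes
#'
#' Strokes are delimited by sign changes of the smoothed vertical velocity
#' (5-sample moving average). Candidate segments are kept only if their
#' vertical excursion is at least `min_amplitude_fraction` of the bar height
#' and their duration is at least `min_duration_s`; sub-threshold wiggles are
#' discarded, so kept strokes alternate in direction.
#'
#' @param trajectory A uniformly sampled trajectory (see
#'   [resample_trajectory()]).
#' @param min_amplitude_fraction Minimum vertical excursion as a fraction of
#'   `bar_height`.
#' @param min_duration_s Minimum stroke duration in seconds.
#' @param geometry A [frame_geometry()] (for the bar height).
#' @return List of `stroke` objects: data.frames (`t_s`, `x_cm`, `y_cm`,
#'   `z_cm`) with attributes `direction` (`"up"`/`"down"`) and `rate_hz`.
#' @export
segment_strokes <- function(trajectory, min_amplitude_fraction = 0.3,
                            min_duration_s = 0.3,
                            geometry = frame_geometry()) {
  tr <- trajectory[trajectory$valid_flag > 0, , drop = FALSE]
  n <- nrow(tr)
  if (n < 10) return(list())
  rate <- attr(trajectory, "rate_hz")
  if (is.null(rate)) rate <- 1 / stats::median(diff(tr$t_s))

  vy <- c(0, diff(tr$y_cm)) * rate
  vy <- stats::filter(vy, rep(1 / 5, 5), sides = 2)
  vy[is.na(vy)] <- 0
  sgn <- sign(vy)
  sgn[sgn == 0] <- NA
  sgn <- zoo_locf(sgn)

  changes <- which(diff(sgn) != 0)
  bounds <- c(1L, changes, n)
  strokes <- list()
  min_amp <- min_amplitude_fraction * geometry$bar_height
  for (i in seq_len(length(bounds) - 1)) {
    idx <- bounds[i]:bounds[i + 1]
    seg <- tr[idx, , drop = FALSE]
    dy <- seg$y_cm[nrow(seg)] - seg$y_cm[1]
    dur <- seg$t_s[nrow(seg)] - seg$t_s[1]
    if (abs(dy) >= min_amp && dur >= min_duration_s && nrow(seg) >= 5) {
      s <- seg[, c("t_s", "x_cm", "y_cm", "z_cm")]
      attr(s, "direction") <- if (dy > 0) "up" else "down"
      attr(s, "rate_hz") <- rate
      class(s) <- c("stroke", class(s))
      strokes[[length(strokes) + 1L]] <- s
    }
  }
  strokes
}

# last-observation-carried-forward for a numeric vector (head NAs backfilled)
zoo_locf <- function(x) {
  idx <- cumsum(!is.na(x))
  filled <- c(NA, x[!is.na(x)])[idx + 1]
  if (anyNA(filled)) {
    first <- filled[which(!is.na(filled))[1]]
    filled[is.na(filled)] <- if (is.na(first)) 1 else first
  }
  filled
}

#' Squared 3D path curvature of a stroke
#'
#' Computes per-sample squared curvature from central finite differences
#' (one-sided at the edges) of the optionally low-pass-filtered position
#' samples:
#' \deqn{\kappa^2 = \frac{|v|^2 |a|^2 - (v \cdot a)^2}{|v|^{2p}}}
#' With the default exponent `p = 3` this is the standard squared geometric
#' curvature of a 3D path (`|v x a|^2 / |v|^6`, units cm^-2), which is
#' invariant to traversal speed; `p = 1` reproduces a dimensionally
#' inconsistent variant that divides by the squared speed only, kept available
#' because some descriptions of the statistic print that form.
#'
#' Samples slower than `speed_floor` use the floor speed in the denominator
#' (preventing blow-up at turning points), and the result is floored at
#' `kappa_floor` before any logarithm; the fraction of samples touched by
#' either clamp is reported.
#'
#' @param stroke A `stroke` (or any data.frame with `t_s`, `x_cm`, `y_cm`,
#'   `z_cm` at uniform sampling).
#' @param p Denominator exponent; see above.
#' @param speed_floor Minimum speed (cm/s) used in the denominator.
#' @param kappa_floor Lower clamp for the squared curvature.
#' @param smooth_hz Cut-off (Hz) of the zero-phase low-pass position filter
#'   applied before differentiation; `NA` disables filtering. Finite
#'   differences amplify measurement noise as the square of the sampling
#'   rate, so raw motion-capture samples need this.
#' @return List of class `curvature_series`: `kappa_sq` (numeric vector),
#'   `clamped_fraction`, `rate_hz`.
#' @export
curvature_sq <- function(stroke, p = 3, speed_floor = 0.5,
                         kappa_floor = 1e-12, smooth_hz = 5) {
  if (nrow(stroke) < 5) stop("stroke too short for second differences")
  rate <- attr(stroke, "rate_hz")
  if (is.null(rate)) rate <- 1 / stats::median(diff(stroke$t_s))
  pos <- as.matrix(stroke[, c("x_cm", "y_cm", "z_cm")])
  if (is.finite(smooth_hz) && smooth_hz < rate / 2 && nrow(pos) > 12) {
    bf <- signal::butter(2, smooth_hz / (rate / 2), type = "low")
    pos <- apply(pos, 2, function(col) signal::filtfilt(bf, col))
  }
  v <- apply(pos, 2, finite_diff, dt = 1 / rate)
  a <- apply(v, 2, finite_diff, dt = 1 / rate)
  v2 <- rowSums(v^2)
  a2 <- rowSums(a^2)
  va <- rowSums(v * a)
  num <- pmax(v2 * a2 - va^2, 0)
  speed2 <- pmax(v2, speed_floor^2)
  kap <- num / speed2^p
  clamped <- (v2 < speed_floor^2) | (kap < kappa_floor)
  kap <- pmax(kap, kappa_floor)
  structure(list(kappa_sq = kap,
                 clamped_fraction = mean(clamped),
                 rate_hz = rate),
            class = "curvature_series")
}

# central finite difference with one-sided differences at the edges
finite_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Per-stroke movement smoothness
#'
#' The median over the stroke of the negative natural log of the squared path
#' curvature: straighter, smoother paths have lower curvature and therefore a
#' higher score.
#'
#' @inheritParams curvature_sq
#' @param ... Passed to [curvature_sq()].
#' @return A single numeric smoothness value (attribute `clamped_fraction`
#'   carries the curvature clamp diagnostics).
#' @export
stroke_smoothness <- function(stroke, ...) {
  cs <- curvature_sq(stroke, ...)
  out <- stats::median(-log(cs$kappa_sq))
  attr(out, "clamped_fraction") <- cs$clamped_fraction
  out
}

#' Build the smoothness modelling table from segmented cohort strokes
#'
#' Takes per-trajectory stroke sets with their metadata and assembles one row
#' per stroke with the modelling covariates: centred two-level codes for group
#' and capture device (-0.5 / +0.5), the session index centred at each
#' patient's median modelled session, and the standardized pre-intervention
#' smoothness `pre.z`, computed per patient as the mean smoothness of the
#' baseline session (lowest session index present, by convention the
#' pre-intervention measurement) and standardized across patients. Baseline
#' session strokes are used only for `pre.z` and are excluded from the
#' returned records. The outcome `MedianLC` is z-scored across all returned
#' records (zero mean, unit SD).
#'
#' @param stroke_sets List; each element is a list with elements `strokes`
#'   (list of strokes, or a numeric vector of pre-computed smoothness values)
#'   and `meta` (list with `patient`, `group` ("treatment"/"control"),
#'   `session` integer, `device` ("inertial"/"optical"), optional `task`).
#' @param first_task_only If `TRUE`, only stroke sets with `meta$task == 1`
#'   enter the table.
#' @param baseline_session Session index regarded as the pre-intervention
#'   measurement (default: the minimum present per patient).
#' @param z_outcome Z-score the outcome across records (default `TRUE`).
#' @param ... Passed to [stroke_smoothness()].
#' @return data.frame with the fixed column order `IDanon`, `Group.c`,
#'   `Session.c`, `pre.z`, `MoCap.c`, `MedianLC` (plus `session` for
#'   reference). Attribute `dropped` lists stroke sets dropped for missing
#'   metadata.
#' @export
build_records <- function(stroke_sets, first_task_only = FALSE,
                          baseline_session = NULL, z_outcome = TRUE, ...) {
  rows <- list()
  dropped <- character(0)
  for (i in seq_along(stroke_sets)) {
    ss <- stroke_sets[[i]]
    m <- ss$meta
    need <- c("patient", "group", "session", "device")
    if (is.null(m) || !all(need %in% names(m)) ||
        any(vapply(m[need], function(v) is.null(v) || is.na(v)[1], TRUE))) {
      dropped <- c(dropped, sprintf("stroke set %d: incomplete metadata", i))
      next
    }
    if (first_task_only && !is.null(m$task) && m$task != 1) next
    vals <- if (is.numeric(ss$strokes)) ss$strokes else
      vapply(ss$strokes, function(s) as.numeric(stroke_smoothness(s, ...)), 0)
    if (length(vals) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      IDanon = as.character(m$patient),
      group = as.character(m$group),
      session = as.integer(m$session),
      device = as.character(m$device),
      MedianLC = vals,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no usable stroke sets")
  df <- do.call(rbind, rows)

  df$Group.c <- ifelse(df$group == "treatment", 0.5, -0.5)
  df$MoCap.c <- ifelse(df$device == "inertial", 0.5, -0.5)

  # pre-intervention smoothness: mean over each patient's baseline session
  pre_raw <- vapply(split(df, df$IDanon), function(d) {
    base <- if (is.null(baseline_session)) min(d$session) else baseline_session
    mean(d$MedianLC[d$session == base])
  }, 0)
  pre_z <- if (length(pre_raw) > 1 && stats::sd(pre_raw) > 0) {
    as.numeric(scale(pre_raw))
  } else {
    rep(0, length(pre_raw))
  }
  names(pre_z) <- names(pre_raw)

  # modelled records exclude the baseline session, except for patients whose
  # only session is the baseline (nothing else to model)
  base_of <- vapply(split(df$session, df$IDanon), min, 0L)
  n_sess <- vapply(split(df$session, df$IDanon),
                   function(s) length(unique(s)), 0L)
  if (!is.null(baseline_session)) base_of[] <- baseline_session
  keep <- df$session > base_of[df$IDanon] | n_sess[df$IDanon] == 1L
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop("no post-baseline records")

  df$pre.z <- pre_z[df$IDanon]
  med_sess <- vapply(split(df$session, df$IDanon), stats::median, 0)
  df$Session.c <- df$session - med_sess[df$IDanon]
  if (z_outcome) {
    s <- stats::sd(df$MedianLC)
    if (!is.finite(s) || s == 0) stop("outcome has zero variance; cannot z-score")
    df$MedianLC <- (df$MedianLC - mean(df$MedianLC)) / s
  }

  out <- df[, c("IDanon", "Group.c", "Session.c", "pre.z", "MoCap.c",
                "MedianLC", "session")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
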