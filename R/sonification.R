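#' Training-frame geometry
#'
#' Describes the wooden training frame: a square board subdivided into a 3 x 3
#' grid of numbered fields, with vertical bars subdivided into equally spaced
#' pitch intervals. Axis convention: `x` runs left to right in front of the
#' patient (timbre axis), `y` is vertical (pitch axis), `z` runs proximal to
#' distal (loudness axis); the origin sits at the patient-side left corner of
#' the board.
#'
#' @param board_size Side length of the square board in cm.
#' @param bar_height Height of the vertical pitch bars in cm.
#' @param n_fields Number of board fields; must be a perfect square.
#' @param n_pitch_intervals Number of equal vertical pitch intervals (>= 2).
#' @return An object of class `frame_geometry`.
#' @export
frame_geometry <- function(board_size = 51, bar_height = 51, n_fields = 9,
                           n_pitch_intervals = 6) {
  stopifnot(board_size > 0, bar_height > 0)
  side <- sqrt(n_fields)
  if (side != round(side)) {
    stop("`n_fields` must be a perfect square (3 x 3 grid by default)")
  }
  if (n_pitch_intervals < 2) stop("`n_pitch_intervals` must be >= 2")
  structure(
    list(board_size = board_size, bar_height = bar_height,
         n_fields = as.integer(n_fields), grid_side = as.integer(side),
         n_pitch_intervals = as.integer(n_pitch_intervals)),
    class = "frame_geometry"
  )
}

#' Default pitch tuning table
#'
#' Frequencies (Hz) of the six pitch intervals, bottom to top. The endpoints
#' are the values used in the training system: c' = 226.6 Hz at the bottom and
#' a' = 440 Hz at the top. Note that 226.6 Hz is not the equal-temperament c'
#' (261.63 Hz when a' = 440 Hz); the system's printed endpoint is kept as-is
#' rather than silently corrected, and the interior notes are filled in from
#' equal temperament anchored at a' = 440 Hz.
#'
#' @param n Number of intervals; only the default 6 has a curated table.
#' @return Numeric vector of frequencies in Hz, strictly increasing.
#' @export
default_tuning <- function(n = 6) {
  if (n == 6) {
    c(226.6, 293.66, 329.63, 349.23, 392.00, 440.00)
  } else {
    # generic fallback: geometric ladder between the same endpoints
    226.6 * (440 / 226.6)^(seq(0, 1, length.out = n))
  }
}

#' Map hand height to a pitch interval and frequency
#'
#' The bar is divided into `n_pitch_intervals` half-open intervals
#' `[low, high)`; the top boundary is closed into the top interval so that a
#' hand at exactly `bar_height` still sounds the highest note.
#'
#' @param height Hand height above the board in cm (vector allowed).
#' @param geometry A [frame_geometry()].
#' @param tuning Frequency table, one entry per interval, strictly increasing.
#' @return A data.frame with columns `pitch_index`, `frequency`, `in_frame`.
#'   Out-of-frame heights (outside `[0, bar_height]`) get `in_frame = FALSE`
#'   and `NA` pitch: no event is emitted for them.
#' @export
map_pitch <- function(height, geometry = frame_geometry(),
                      tuning = default_tuning(geometry$n_pitch_intervals)) {
  n <- geometry$n_pitch_intervals
  if (length(tuning) != n) stop("tuning table length must equal n_pitch_intervals")
  if (any(diff(tuning) <= 0)) stop("tuning table must be strictly increasing")
  width <- geometry$bar_height / n
  k <- floor(height / width) + 1
  k[height == geometry$bar_height] <- n  # top boundary closed
  in_frame <- height >= 0 & height <= geometry$bar_height
  k[!in_frame] <- NA_integer_
  data.frame(pitch_index = as.integer(k),
             frequency = ifelse(in_frame, tuning[k], NA_real_),
             in_frame = in_frame)
}

#' Locate a hand position on the board
#'
#' Maps the horizontal position to a board field (3 x 3 grid, row-major with
#' row 1 nearest the patient, field 1 at the patient's near-left corner), a
#' timbre zone from the x thirds (left = clarinet, middle = saxophone,
#' right = bowed), and a loudness attenuation from the z axis: 0 dB when
#' proximal, ramping linearly to `-loudness_range_db` at the far edge.
#'
#' @param x,z Board-plane coordinates in cm (vectors allowed).
#' @param geometry A [frame_geometry()].
#' @param loudness_range_db Total loudness ramp in dB (positive number).
#' @return data.frame with `field_index`, `timbre_zone`, `loudness_db`,
#'   `in_frame`.
#' @export
locate <- function(x, z, geometry = frame_geometry(), loudness_range_db = 20) {
  side <- geometry$grid_side
  b <- geometry$board_size
  in_frame <- x >= 0 & x <= b & z >= 0 & z <= b
  cell <- function(u) pmin(floor(u / (b / side)) + 1, side)
  col <- cell(pmax(pmin(x, b), 0))
  row <- cell(pmax(pmin(z, b), 0))
  field <- (row - 1L) * side + col
  timbres <- c("clarinet", "saxophone", "bowed")
  tz <- timbres[pmin(floor(x / (b / 3)) + 1, 3)]
  loud <- -(z / b) * loudness_range_db
  field[!in_frame] <- NA_integer_
  tz[!in_frame] <- NA_character_
  loud[!in_frame] <- NA_real_
  data.frame(field_index = as.integer(field), timbre_zone = tz,
             loudness_db = loud, in_frame = in_frame)
}

#' Sonify a trajectory into a discrete event stream
#'
#' Walks a uniformly sampled trajectory and emits a new note event whenever
#' the pitch interval, the timbre zone, or the board field changes, closing
#' the previous event. Pitch changes are debounced: a boundary crossing only
#' registers once the hand has moved past the boundary by
#' `hysteresis_fraction` of one interval height, so jitter around a boundary
#' does not produce note chatter. A stationary hand sustains a single event;
#' out-of-frame samples close the current event and emit nothing.
#'
#' @param trajectory A trajectory data.frame (see [gen_trajectory()]) with
#'   columns `t_s`, `x_cm`, `y_cm`, `z_cm`, and optionally `valid_flag`.
#' @param geometry A [frame_geometry()].
#' @param tuning Frequency table.
#' @param hysteresis_fraction Fraction of one interval height (in `[0, 0.5)`)
#'   a boundary must be exceeded by before a pitch change registers.
#' @return An `event_stream`: data.frame with columns `onset_s`, `offset_s`,
#'   `pitch_index`, `frequency`, `field_index`, `timbre_zone`, `loudness_db`.
#' @export
sonify <- function(trajectory, geometry = frame_geometry(),
                   tuning = default_tuning(geometry$n_pitch_intervals),
                   hysteresis_fraction = 0.05) {
  if (hysteresis_fraction < 0 || hysteresis_fraction >= 0.5) {
    stop("`hysteresis_fraction` must lie in [0, 0.5)")
  }
  if (is.null(trajectory) || nrow(trajectory) == 0) return(empty_event_stream())
  if (!is.null(trajectory$valid_flag)) {
    trajectory <- trajectory[trajectory$valid_flag > 0, , drop = FALSE]
  }
  if (nrow(trajectory) == 0) return(empty_event_stream())

  n_int <- geometry$n_pitch_intervals
  width <- geometry$bar_height / n_int
  hys <- hysteresis_fraction * width
  pit <- map_pitch(trajectory$y_cm, geometry, tuning)
  loc <- locate(trajectory$x_cm, trajectory$z_cm, geometry)
  in_frame <- pit$in_frame & loc$in_frame

  events <- list()
  cur <- NULL  # active event state
  open_evt <- function(i, pitch) {
    list(onset = trajectory$t_s[i], pitch = pitch,
         freq = tuning[pitch], field = loc$field_index[i],
         timbre = loc$timbre_zone[i], loud = loc$loudness_db[i])
  }
  close_evt <- function(cur, t_off) {
    data.frame(onset_s = cur$onset, offset_s = t_off,
               pitch_index = cur$pitch, frequency = cur$freq,
               field_index = cur$field, timbre_zone = cur$timbre,
               loudness_db = cur$loud, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(trajectory))) {
    if (!in_frame[i]) {
      if (!is.null(cur)) {
        events[[length(events) + 1L]] <- close_evt(cur, trajectory$t_s[i])
        cur <- NULL
      }
      next
    }
    if (is.null(cur)) {
      cur <- open_evt(i, pit$pitch_index[i])
      next
    }
    # debounced pitch: only leave the current interval once past the
    # boundary by `hys`
    y <- trajectory$y_cm[i]
    lo <- (cur$pitch - 1) * width
    hi <- cur$pitch * width
    new_pitch <- cur$pitch
    if (y >= hi + hys || y < lo - hys) {
      new_pitch <- pit$pitch_index[i]
    }
    changed <- new_pitch != cur$pitch ||
      loc$field_index[i] != cur$field ||
      loc$timbre_zone[i] != cur$timbre
    if (changed) {
      events[[length(events) + 1L]] <- close_evt(cur, trajectory$t_s[i])
      cur <- open_evt(i, new_pitch)
    }
  }
  if (!is.null(cur)) {
    last_t <- trajectory$t_s[nrow(trajectory)]
    dt <- if (nrow(trajectory) > 1) stats::median(diff(trajectory$t_s)) else 0
    events[[length(events) + 1L]] <- close_evt(cur, last_t + dt)
  }
  if (length(events) == 0) return(empty_event_stream())
  out <- do.call(rbind, events)
  class(out) <- c("event_stream", class(out))
  out
}

empty_event_stream <- function() {
  out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                    pitch_index = integer(0), frequency = numeric(0),
                    field_index = integer(0), timbre_zone = character(0),
                    loudness_db = numeric(0))
  class(out) <- c("event_stream", class(out))
  out
}

#' Idealized event stream for a task
#'
#' Renders the reference (target) event stream for a task: one event per note
#' of the note sequence, with consecutive repeats of the same note merged
#' within a repetition (legato: the shared note at the turning point of an
#' up-down scale is sustained, not re-struck) and uniform note durations.
#' Repetitions are kept separate: each repetition re-articulates its first
#' note even if it equals the last note of the previous repetition.
#'
#' @param task A [task_spec()].
#' @param geometry A [frame_geometry()].
#' @param tuning Frequency table.
#' @param note_duration_s Duration of each event in seconds.
#' @return An `event_stream` (see [sonify()]).
#' @export
task_events <- function(task, geometry = frame_geometry(),
                        tuning = default_tuning(geometry$n_pitch_intervals),
                        note_duration_s = 1) {
  seq1 <- task$note_sequence[c(TRUE, diff(task$note_sequence) != 0)]
  pitches <- rep(list(seq1), task$repetitions)
  pitches <- unlist(pitches)
  n <- length(pitches)
  onset <- (seq_len(n) - 1) * note_duration_s
  fl <- field_center(task$position_field, geometry)
  loc <- locate(fl["x"], fl["z"], geometry)
  out <- data.frame(onset_s = onset, offset_s = onset + note_duration_s,
                    pitch_index = as.integer(pitches),
                    frequency = tuning[pitches],
                    field_index = rep(loc$field_index, n),
                    timbre_zone = rep(loc$timbre_zone, n),
                    loudness_db = rep(loc$loudness_db, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_stream", class(out))
  out
}

# centre (x, z) of a board field under the row-major numbering
field_center <- function(field_index, geometry = frame_geometry()) {
  side <- geometry$grid_side
  if (field_index < 1 || field_index > geometry$n_fields) {
    stop("field index outside the board")
  }
  row <- (field_index - 1) %/% side + 1
  col <- (field_index - 1) %% side + 1
  w <- geometry$board_size / side
  c(x = (col - 0.5) * w, z = (row - 0.5) * w)
}

# centre height (cm) of a pitch interval
interval_center <- function(pitch_index, geometry = frame_geometry()) {
  w <- geometry$bar_height / geometry$n_pitch_intervals
  (pitch_index - 0.5) * w
}
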