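#' Write / read a trajectory as delimited text
#'
#' Column schema: `t_s, x_cm, y_cm, z_cm, valid_flag`. A provenance header of
#' `#`-prefixed comment lines records the sampling metadata and, when given,
#' the seed and configuration hash, so every output file carries its
#' provenance.
#'
#' @param trajectory A trajectory data.frame.
#' @param path Output path.
#' @param provenance Named list written into the comment header.
#' @return `path` invisibly (writer); a `trajectory` (reader, with the
#'   provenance header in `attr(, "provenance")`).
#' @export
write_trajectory <- function(trajectory, path, provenance = list()) {
  provenance <- c(list(schema = "trajectory-v1",
                       rate_hz = attr(trajectory, "rate_hz"),
                       dialect = attr(trajectory, "dialect")),
                  provenance)
  hdr <- vapply(names(provenance), function(k)
    sprintf("# %s: %s", k, format(provenance[[k]])), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(
    data.frame(t_s = round(trajectory$t_s, 6),
               x_cm = round(trajectory$x_cm, 6),
               y_cm = round(trajectory$y_cm, 6),
               z_cm = round(trajectory$z_cm, 6),
               valid_flag = trajectory$valid_flag),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trajectory file: ", path)
  hdr <- grep("^#", lines)
  body <- if (length(hdr)) lines[-hdr] else lines
  if (length(body) < 2) stop("trajectory file has no data rows: ", path)
  df <- tryCatch(
    utils::read.csv(text = body),
    warning = function(w) stop("malformed trajectory file: ", conditionMessage(w)),
    error = function(e) stop("malformed trajectory file: ", conditionMessage(e)))
  need <- c("t_s", "x_cm", "y_cm", "z_cm", "valid_flag")
  if (!all(need %in% names(df))) {
    stop("trajectory file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  for (cl in need) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  bad <- which(!stats::complete.cases(df[, need]))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s",
                 bad[1] + length(hdr) + 1L, path))
  }
  prov <- list()
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv)
    prov[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  if (!is.null(prov$rate_hz)) attr(df, "rate_hz") <- as.numeric(prov$rate_hz)
  if (!is.null(prov$dialect) && prov$dialect != "NULL") {
    attr(df, "dialect") <- prov$dialect
  }
  attr(df, "provenance") <- prov
  class(df) <- c("trajectory", class(df))
  df
}

#' Write an event stream
#'
#' Two formats: JSON lines (one event object per line, keys `onset_s`,
#' `offset_s`, `pitch_index`, `frequency`, `field_index`, `timbre_zone`,
#' `loudness_db`) and Standard MIDI File (format 0, one track; frequency is
#' mapped to the nearest MIDI note, loudness to velocity 1-127, timbre zone
#' to a program number).
#'
#' @param stream An `event_stream`.
#' @param path Output path; the format is inferred from the extension
#'   (`.jsonl` or `.mid`) unless given explicitly.
#' @param format `"jsonl"` or `"midi"`.
#' @return `path` invisibly.
#' @export
write_events <- function(stream, path, format = c("auto", "jsonl", "midi")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.midi?$", path, ignore.case = TRUE)) "midi" else "jsonl"
  }
  if (format == "jsonl") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(stream))) {
      writeLines(jsonlite::toJSON(as.list(stream[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  } else {
    write_midi(stream, path)
  }
  invisible(path)
}

#' Read a JSON-lines event stream
#' @param path Path of a `.jsonl` events file.
#' @return An `event_stream` data.frame.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_event_stream())
  rows <- lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  class(out) <- c("event_stream", class(out))
  out
}

# --- minimal Standard MIDI File (format 0) writer ------------------------

midi_varlen <- function(x) {
  bytes <- as.raw(x %% 128)
  x <- x %/% 128
  while (x > 0) {
    bytes <- c(as.raw(128 + x %% 128), bytes)
    x <- x %/% 128
  }
  bytes
}

freq_to_midi <- function(f) as.integer(round(69 + 12 * log2(f / 440)))

write_midi <- function(stream, path, ticks_per_quarter = 480,
                       us_per_quarter = 500000) {
  programs <- c(clarinet = 71L, saxophone = 65L, bowed = 40L)
  # event list: (tick, raw message)
  tick_of <- function(t_s) round(t_s * 1e6 / us_per_quarter * ticks_per_quarter)
  msgs <- list()
  for (i in seq_len(nrow(stream))) {
    note <- freq_to_midi(stream$frequency[i])
    vel <- as.integer(round(1 + 126 * 10^(stream$loudness_db[i] / 20)))
    vel <- max(1L, min(127L, vel))
    prog <- programs[[stream$timbre_zone[i]]]
    msgs[[length(msgs) + 1L]] <- list(tick = tick_of(stream$onset_s[i]),
                                      ord = 0L,
                                      raw = as.raw(c(0xC0, prog)))
    msgs[[length(msgs) + 1L]] <- list(tick = tick_of(stream$onset_s[i]),
                                      ord = 1L,
                                      raw = as.raw(c(0x90, note, vel)))
    msgs[[length(msgs) + 1L]] <- list(tick = tick_of(stream$offset_s[i]),
                                      ord = 0L,
                                      raw = as.raw(c(0x80, note, 64)))
  }
  ord <- order(vapply(msgs, function(m) m$tick, 0),
               vapply(msgs, function(m) m$ord, 0L))
  msgs <- msgs[ord]
  track <- raw(0)
  last <- 0
  for (m in msgs) {
    track <- c(track, midi_varlen(m$tick - last), m$raw)
    last <- m$tick
  }
  track <- c(track, midi_varlen(0), as.raw(c(0xFF, 0x2F, 0x00)))  # end of track

  int_be <- function(x, n) as.raw(rev((x %/% 256^(0:(n - 1))) %% 256))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), int_be(6, 4), int_be(0, 2), int_be(1, 2),
             int_be(ticks_per_quarter, 2),
             charToRaw("MTrk"), int_be(length(track), 4), track), con)
  invisible(path)
}

# parse note-on/note-off pairs back out of a format-0 SMF written by
# write_midi (round-trip checking; not a general MIDI reader)
read_midi_notes <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  stopifnot(rawToChar(raw[1:4]) == "MThd")
  tpq <- as.integer(raw[13]) * 256L + as.integer(raw[14])
  i <- 23  # first byte after the MTrk length field
  notes <- list(); open <- list()
  tick <- 0
  n <- length(raw)
  while (i <= n) {
    # variable-length delta time
    dt <- 0
    repeat {
      b <- as.integer(raw[i]); i <- i + 1
      dt <- dt * 128 + (b %% 128)
      if (b < 128) break
    }
    tick <- tick + dt
    status <- as.integer(raw[i])
    if (status == 0xFF) break                   # end-of-track meta
    if (status >= 0xC0 && status <= 0xCF) {
      i <- i + 2
    } else {
      note <- as.integer(raw[i + 1]); vel <- as.integer(raw[i + 2])
      if (status >= 0x90 && status <= 0x9F && vel > 0) {
        open[[as.character(note)]] <- tick
      } else {
        on_t <- open[[as.character(note)]]
        notes[[length(notes) + 1L]] <- data.frame(
          note = note, onset_tick = on_t, offset_tick = tick)
        open[[as.character(note)]] <- NULL
      }
      i <- i + 3
    }
  }
  out <- if (length(notes)) do.call(rbind, notes) else
    data.frame(note = integer(0), onset_tick = numeric(0),
               offset_tick = numeric(0))
  attr(out, "ticks_per_quarter") <- tpq
  out
}

#' Write a records or summary table as delimited text with provenance
#'
#' @param df Data frame.
#' @param path Output path.
#' @param provenance Named list written as `#`-prefixed header lines.
#' @return `path` invisibly.
#' @export
write_table_prov <- function(df, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, format(provenance[[k]])), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table_prov()]
#' @param path File path.
#' @return data.frame with `attr(, "provenance")`.
#' @export
read_table_prov <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  df <- utils::read.csv(text = if (length(hdr)) lines[-hdr] else lines)
  prov <- list()
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    prov[[sub(":.*$", "", kv)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  attr(df, "provenance") <- prov
  df
}
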