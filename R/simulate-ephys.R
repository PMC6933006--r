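#' The packaged 20-channel 10-20 montage
#'
#' Schematic 2D head layout (unit head radius, nose up) of the 19 standard
#' 10-20 scalp positions plus Oz, the set used for the EEG recordings.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
montage_1020 <- function() {
  ring <- function(name, deg) {
    data.frame(channel = name, x = sinpi(deg / 180), y = cospi(deg / 180))
  }
  rbind(
    ring("Fp1", -18), ring("Fp2", 18),
    ring("F7", -54), ring("F8", 54),
    ring("T3", -90), ring("T4", 90),
    ring("T5", -126), ring("T6", 126),
    ring("O1", -162), ring("O2", 162), ring("Oz", 180),
    data.frame(channel = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                           "P3", "Pz", "P4"),
               x = c(-0.4, 0, 0.4, -0.5, 0, 0.5, -0.4, 0, 0.4),
               y = c(0.52, 0.5, 0.52, 0, 0, 0, -0.52, -0.5, -0.52))
  )
}

#' Cortico-muscular coupling design for the ephys generator
#'
#' @param coupling_strength Mixing weight in `[0, 1]` of the lagged cortical
#'   beta component in the EMG: 1 = perfectly phase-locked, 0 = independent.
#' @param coupled_channels EEG channels (10-20 names) carrying the beta
#'   oscillation that drives the muscle.
#' @param beta_freq Oscillation frequency in Hz, within the low beta band
#'   14-20 Hz.
#' @param lag Cortex-to-muscle conduction delay in seconds (> 0). The default
#'   15 ms keeps the interaction phase well inside one quadrant across the
#'   band.
#' @param n_trials Number of self-paced arm elevations (~one per 5 s).
#' @param noise_sd Background noise SD in microvolts.
#' @param seed Integer seed.
#' @return A `coupling_design` object.
#' @export
coupling_design <- function(coupling_strength = 0.8,
                            coupled_channels = "C3", beta_freq = 17,
                            lag = 0.015, n_trials = 100, noise_sd = 10,
                            seed = 1) {
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("`coupling_strength` must lie in [0, 1]")
  }
  bad <- setdiff(coupled_channels, montage_1020()$channel)
  if (length(bad)) {
    stop("coupled channel(s) not in the 10-20 montage: ",
         paste(bad, collapse = ", "))
  }
  if (beta_freq < 14 || beta_freq > 20) stop("`beta_freq` must be in 14-20 Hz")
  if (lag <= 0) stop("`lag` must be positive")
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  structure(list(coupling_strength = coupling_strength,
                 coupled_channels = coupled_channels, beta_freq = beta_freq,
                 lag = lag, n_trials = as.integer(n_trials),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "coupling_design")
}

# 1/f-shaped noise via spectral shaping of white noise
pink_noise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # mirror for the negative freqs
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' Generate a synthetic EEG+EMG recording with beta-band coupling
#'
#' 200 Hz recording of 20 EEG channels (10-20 montage) and one deltoid EMG
#' channel during `n_trials` self-paced arm elevations spaced ~5 s apart.
#' Each trial injects a beta oscillation with a fresh random phase into the
#' coupled EEG channels; the EMG receives, inside its burst envelope, a
#' mixture of that oscillation delayed by `lag` (weight `coupling_strength`)
#' and an independent-phase oscillation (weight `1 - coupling_strength`),
#' on top of envelope-modulated broadband muscle noise. EEG background is
#' 1/f noise scaled by `noise_sd`; EMG noise amplitudes also scale with
#' `noise_sd` so the zero-noise limit is a clean phase-locked pair.
#'
#' @param design A [coupling_design()].
#' @param rate Sampling rate in Hz.
#' @param beta_amp_uv Beta amplitude in the EEG (microvolts).
#' @param emg_beta_amp_uv Beta amplitude in the EMG.
#' @return An `ephys_recording`: list with `eeg` (channels x samples matrix,
#'   10-20 rownames), `emg` (1 x samples, rowname `DELT`), `rate`, `events`
#'   (onset sample indices), `channels`.
#' @export
gen_ephys <- function(design, rate = 200, beta_amp_uv = 5,
                      emg_beta_amp_uv = 30) {
  set.seed(design$seed)
  mon <- montage_1020()
  n_tr <- design$n_trials
  spacing <- 5
  dur <- n_tr * spacing + 5
  n <- round(dur * rate)
  t <- seq_len(n) / rate

  onsets_s <- 2.5 + (seq_len(n_tr) - 1) * spacing +
    stats::runif(n_tr, -0.4, 0.4)
  events <- round(onsets_s * rate)

  eeg <- matrix(0, nrow(mon), n, dimnames = list(mon$channel, NULL))
  for (ci in seq_len(nrow(mon))) eeg[ci, ] <- pink_noise(n, design$noise_sd)

  # per-trial burst envelope: raised cosine from +0.25 s to +2.25 s
  env <- numeric(n)
  burst <- function(on) {
    i0 <- round((on + 0.25) * rate); i1 <- round((on + 2.25) * rate)
    i0 <- max(i0, 1); i1 <- min(i1, n)
    w <- i1 - i0 + 1
    list(idx = i0:i1, win = 0.5 - 0.5 * cos(2 * pi * seq_len(w) / w))
  }

  # sharp-onset EMG contraction envelope: the burst starts at the event
  # marker (60 ms rise), holds ~2.2 s, releases over 0.3 s
  emg_burst <- function(on) {
    i0 <- max(round(on * rate), 1)
    ramp_n <- round(0.04 * rate); hold_n <- round(2.2 * rate)
    fall_n <- round(0.3 * rate)
    win <- c(seq(0, 1, length.out = ramp_n), rep(1, hold_n),
             seq(1, 0, length.out = fall_n))
    idx <- i0:min(i0 + length(win) - 1L, n)
    list(idx = idx, win = win[seq_along(idx)])
  }

  w_beta <- 2 * pi * design$beta_freq
  phases <- stats::runif(n_tr, 0, 2 * pi)
  phases_ind <- stats::runif(n_tr, 0, 2 * pi)
  emg_beta <- numeric(n)
  c_s <- design$coupling_strength
  for (k in seq_len(n_tr)) {
    bw <- burst(onsets_s[k])
    tt <- t[bw$idx]
    osc <- bw$win * cos(w_beta * tt + phases[k])
    for (chn in design$coupled_channels) {
      eeg[chn, bw$idx] <- eeg[chn, bw$idx] + beta_amp_uv * osc
    }
    eb <- emg_burst(onsets_s[k])
    env[eb$idx] <- env[eb$idx] + eb$win
    lagged <- bw$win * cos(w_beta * (tt - design$lag) + phases[k])
    indep <- bw$win * cos(w_beta * tt + phases_ind[k])
    emg_beta[bw$idx] <- emg_beta[bw$idx] +
      emg_beta_amp_uv * (c_s * lagged + (1 - c_s) * indep)
  }

  emg_noise <- stats::rnorm(n) * (0.5 * design$noise_sd + 8 * design$noise_sd * env)
  emg <- matrix(emg_noise + emg_beta, 1, n, dimnames = list("DELT", NULL))

  structure(list(eeg = eeg, emg = emg, rate = rate,
                 events = as.integer(events),
                 channels = rownames(eeg)),
            class = "ephys_recording")
}

#' Write / read an ephys recording as delimited text plus a JSON sidecar
#'
#' The array container is a plain CSV of samples by channels; the sidecar
#' manifest records channel names, sampling rate and event sample indices.
#'
#' @param rec An `ephys_recording`.
#' @param path Path of the CSV file; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly (writer); an `ephys_recording` (reader).
#' @export
write_ephys <- function(rec, path) {
  dat <- t(rbind(rec$eeg, rec$emg))
  utils::write.csv(as.data.frame(dat), path, row.names = FALSE)
  sidecar <- list(rate = rec$rate,
                  eeg_channels = rownames(rec$eeg),
                  emg_channels = rownames(rec$emg),
                  events = rec$events)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ephys
#' @export
read_ephys <- function(path) {
  dat <- as.matrix(utils::read.csv(path, check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(eeg = t(dat[, side$eeg_channels, drop = FALSE]),
                 emg = t(dat[, side$emg_channels, drop = FALSE]),
                 rate = side$rate, events = as.integer(side$events),
                 channels = side$eeg_channels),
            class = "ephys_recording")
}
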