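#' Preprocess an EEG+EMG recording
#'
#' The standard chain, applied to every channel in order: linear detrend;
#' 2-80 Hz band-pass; 1-80 Hz 3rd-order Butterworth band-pass applied
#' forward-backward (zero phase); 49-51 Hz band-stop (line-noise notch).
#' All filters are zero-phase Butterworth; channel order is preserved.
#'
#' @param rec An `ephys_recording`.
#' @return The filtered recording.
#' @export
preprocess <- function(rec) {
  nyq <- rec$rate / 2
  if (nyq <= 80) {
    stop("sampling rate too low for the 80 Hz filter corner (Nyquist limit)")
  }
  bp1 <- signal::butter(3, c(2, 80) / nyq, type = "pass")
  bp2 <- signal::butter(3, c(1, 80) / nyq, type = "pass")
  notch <- signal::butter(3, c(49, 51) / nyq, type = "stop")
  clean <- function(x) {
    n <- length(x)
    tt <- seq_len(n)
    x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
    x <- signal::filtfilt(bp1, x)
    x <- signal::filtfilt(bp2, x)
    signal::filtfilt(notch, x)
  }
  rec$eeg <- t(apply(rec$eeg, 1, clean))
  rec$emg <- t(apply(rec$emg, 1, clean))
  rownames(rec$eeg) <- rec$channels
  rec
}

#' Detect EMG burst onsets
#'
#' Rectifies the EMG, smooths it with a moving-average envelope, and marks an
#' onset at each upward threshold crossing, with a refractory lockout so one
#' movement produces one marker.
#'
#' @param emg Numeric vector (one EMG channel, microvolts) or an
#'   `ephys_recording` (first EMG channel used).
#' @param threshold_uv Onset threshold in microvolts; the working range used
#'   in practice is 30-110 depending on individual noise levels.
#' @param refractory_s Lockout after each onset (movements are ~5 s apart).
#' @param rate Sampling rate (taken from the recording when one is given).
#' @param envelope_s Moving-average window of the rectified envelope.
#' @return Integer vector of onset sample indices (possibly empty).
#' @export
detect_onsets <- function(emg, threshold_uv = 30, refractory_s = 3,
                          rate = NULL, envelope_s = 0.05) {
  if (inherits(emg, "ephys_recording")) {
    rate <- emg$rate
    emg <- emg$emg[1, ]
  }
  if (is.null(rate)) stop("`rate` required when passing a bare vector")
  if (refractory_s <= 0) stop("`refractory_s` must be positive")
  w <- max(round(envelope_s * rate), 1)
  env <- stats::filter(abs(emg), rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  above <- env >= threshold_uv
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  onsets <- integer(0)
  last <- -Inf
  half <- threshold_uv / 2
  for (i in crossings) {
    if ((i - last) / rate >= refractory_s) {
      # backtrack to the burst foot (envelope above half threshold), at most
      # 40 ms: zero-phase filtering spreads burst energy slightly backwards
      j <- i
      lim <- max(i - round(0.04 * rate), 1)
      while (j > lim && env[j - 1] > half) j <- j - 1
      onsets <- c(onsets, j)
      last <- i
    }
  }
  onsets
}

#' Epoch a recording around event markers
#'
#' Cuts per-event slices of all channels (EEG then EMG) and applies an
#' automated artifact criterion in place of visual inspection: trials whose
#' EEG peak-to-peak amplitude exceeds `reject_uvpp` on any channel are
#' rejected. Events whose window does not fit inside the recording are
#' dropped. All rejections are returned with reasons.
#'
#' @param rec A (preprocessed) `ephys_recording`.
#' @param events Onset sample indices (default: the recording's markers).
#' @param window Epoch window in seconds relative to each onset.
#' @param reject_uvpp EEG peak-to-peak rejection criterion in microvolts;
#'   `Inf` disables rejection.
#' @return A `trial_set`: list with `epochs` (trials x channels x samples
#'   array, channel dimnames), `window`, `rate`, `eeg_channels`,
#'   `emg_channels`, `rejected` (data.frame of dropped trials with reasons).
#' @export
epoch_recording <- function(rec, events = rec$events, window = c(-1, 2),
                            reject_uvpp = 150) {
  dat <- rbind(rec$eeg, rec$emg)
  n <- ncol(dat)
  i0 <- round(window[1] * rec$rate)
  i1 <- round(window[2] * rec$rate) - 1L
  len <- i1 - i0 + 1L
  keep <- list(); rejected <- list()
  n_eeg <- nrow(rec$eeg)
  for (k in seq_along(events)) {
    a <- events[k] + i0; b <- events[k] + i1
    if (a < 1 || b > n) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(trial = k, reason = "window outside recording")
      next
    }
    ep <- dat[, a:b, drop = FALSE]
    ptp <- apply(ep[seq_len(n_eeg), , drop = FALSE], 1,
                 function(x) diff(range(x)))
    if (any(ptp > reject_uvpp)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(trial = k, reason = sprintf(
          "EEG peak-to-peak %.0f uV exceeds %.0f uV",
          max(ptp), reject_uvpp))
      next
    }
    keep[[length(keep) + 1L]] <- ep
  }
  if (length(keep) == 0) stop("no epochs survived")
  epochs <- array(NA_real_, c(length(keep), nrow(dat), len),
                  dimnames = list(NULL, rownames(dat), NULL))
  for (k in seq_along(keep)) epochs[k, , ] <- keep[[k]]
  structure(list(epochs = epochs, window = window, rate = rec$rate,
                 eeg_channels = rownames(rec$eeg),
                 emg_channels = rownames(rec$emg),
                 rejected = if (length(rejected)) do.call(rbind, rejected)
                 else data.frame(trial = integer(0), reason = character(0))),
            class = "trial_set")
}

# Hann-tapered FFT cross-spectral imaginary parts between every EEG channel
# and one EMG channel, restricted to the band. Returns a list with the
# imaginary parts (trials x bins x channels), their absolute cross-spectral
# magnitudes, and the bin frequencies.
cross_imag <- function(trials, emg_channel = "DELT", band = c(14, 20)) {
  ep <- trials$epochs
  n_tr <- dim(ep)[1]; len <- dim(ep)[3]
  chans <- trials$eeg_channels
  freqs <- (seq_len(len) - 1) * trials$rate / len
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (length(bins) == 0) stop("no frequency bins inside the band")
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
  im <- array(NA_real_, c(n_tr, length(bins), length(chans)))
  xmag <- array(NA_real_, c(n_tr, length(bins), length(chans)))
  for (k in seq_len(n_tr)) {
    emg_f <- stats::fft(ep[k, emg_channel, ] * taper)[bins]
    eeg_mat <- ep[k, chans, , drop = TRUE] *
      matrix(taper, length(chans), len, byrow = TRUE)
    eeg_f <- t(stats::mvfft(t(eeg_mat)))[, bins, drop = FALSE]
    cross <- eeg_f * matrix(Conj(emg_f), length(chans), length(bins),
                            byrow = TRUE)
    im[k, , ] <- t(Im(cross))
    xmag[k, , ] <- t(Mod(cross))
  }
  list(im = im, xmag = xmag, channels = chans, freqs = freqs[bins])
}

#' Weighted phase lag index between EEG channels and an EMG channel
#'
#' Per trial, Hann-tapered FFT cross-spectra between each EEG channel and the
#' EMG are computed and the imaginary parts of all (trial, frequency-bin)
#' pairs within the band are pooled:
#' `WPLI = |sum Im(Sxy)| / sum |Im(Sxy)|`, a value in `[0, 1]` that ignores
#' zero-lag (volume-conducted) interactions. When the total imaginary energy
#' is negligible relative to the cross-spectral magnitude (zero-lag identical
#' signals) the WPLI is defined as 0. A leave-one-trial-out jackknife
#' provides the variance, and the significance flag tests the debiased
#' (pairwise) estimator — which is centred at zero for independent signals —
#' against zero at the two-sided 95% level.
#'
#' @param trials A `trial_set` with at least 10 trials.
#' @param emg_channel EMG channel name.
#' @param band Frequency band in Hz (must lie inside the filter passband).
#' @return A `wpli_map` data.frame: `channel`, `wpli`, `wpli_debiased`,
#'   `jack_var`, `significant`. Attribute `pseudovalues` holds the
#'   trials-by-channels jackknife pseudovalue matrix used by the cluster
#'   statistics.
#' @export
wpli <- function(trials, emg_channel = "DELT", band = c(14, 20)) {
  if (band[1] < 1 || band[2] > 80) {
    stop("band lies outside the 1-80 Hz filter passband")
  }
  if (dim(trials$epochs)[1] < 10) stop("need at least 10 trials")
  cs <- cross_imag(trials, emg_channel, band)
  n_tr <- dim(cs$im)[1]
  # per-trial sums over bins
  s_t <- apply(cs$im, c(1, 3), sum)          # trials x channels: sum Im
  a_t <- apply(abs(cs$im), c(1, 3), sum)     #                   sum |Im|
  q_t <- apply(cs$im^2, c(1, 3), sum)        #                   sum Im^2
  m_t <- apply(cs$xmag, c(1, 3), sum)        #                   sum |Sxy|
  S <- colSums(s_t); A <- colSums(a_t); Q <- colSums(q_t); M <- colSums(m_t)

  raw_wpli <- ifelse(A > 1e-9 * M, abs(S) / A, 0)
  deb <- ifelse(A^2 - Q > 0 & A > 1e-9 * M, (S^2 - Q) / (A^2 - Q), 0)

  # leave-one-trial-out
  loo_w <- sweep(-s_t, 2, S, "+")
  loo_a <- sweep(-a_t, 2, A, "+")
  loo_q <- sweep(-q_t, 2, Q, "+")
  theta_i <- abs(loo_w) / pmax(loo_a, 1e-300)
  deb_i <- (loo_w^2 - loo_q) / pmax(loo_a^2 - loo_q, 1e-300)
  jack_var <- apply(theta_i, 2, function(v) (n_tr - 1) / n_tr *
                      sum((v - mean(v))^2))
  jack_var_deb <- apply(deb_i, 2, function(v) (n_tr - 1) / n_tr *
                          sum((v - mean(v))^2))
  zero_lag <- !(A > 1e-9 * M)
  sig <- !zero_lag & deb / sqrt(pmax(jack_var_deb, 1e-300)) > stats::qnorm(0.975)
  pseudo <- sweep(-(n_tr - 1) * theta_i, 2, n_tr * raw_wpli, "+")

  out <- data.frame(channel = cs$channels, wpli = raw_wpli,
                    wpli_debiased = deb, jack_var = jack_var,
                    significant = sig, row.names = NULL)
  attr(out, "pseudovalues") <- pseudo
  attr(out, "band") <- band
  attr(out, "n_trials") <- n_tr
  class(out) <- c("wpli_map", class(out))
  out
}

#' Channel adjacency for the packaged 10-20 montage
#'
#' Euclidean-distance adjacency on the schematic 2D layout, with the default
#' threshold chosen so the mean neighbour count lies in 3-5. Symmetric, no
#' self-neighbours.
#'
#' @param montage Layout data.frame (see [montage_1020()]).
#' @param threshold Distance threshold on the unit-head layout.
#' @param channels Restrict/validate to these channels.
#' @return Logical adjacency matrix with channel dimnames.
#' @export
neighbors_1020 <- function(montage = montage_1020(), threshold = 0.63,
                           channels = montage$channel) {
  unknown <- setdiff(channels, montage$channel)
  if (length(unknown)) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  }
  mon <- montage[match(channels, montage$channel), ]
  d <- as.matrix(stats::dist(mon[, c("x", "y")]))
  adj <- d > 0 & d <= threshold
  dimnames(adj) <- list(channels, channels)
  adj
}

# per-trial coupling statistic for the cluster test: the band-pooled
# normalized imaginary cross-spectrum u_t = sum(Im) / sum(|Im|) in [-1, 1].
# Unlike jackknife pseudovalues of the WPLI, the u_t are independent across
# trials, so permuting condition labels is exact under the null.
wpli_trial_stats <- function(trials, emg_channel = "DELT", band = c(14, 20)) {
  cs <- cross_imag(trials, emg_channel, band)
  s_t <- apply(cs$im, c(1, 3), sum)
  a_t <- apply(abs(cs$im), c(1, 3), sum)
  u <- s_t / pmax(a_t, 1e-300)
  colnames(u) <- cs$channels
  u
}

# connected components of a channel set under an adjacency matrix
components_of <- function(members, adj) {
  comps <- list()
  left <- members
  while (length(left)) {
    queue <- left[1]; comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- intersect(colnames(adj)[adj[v, ]], left)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1L]] <- comp
    left <- setdiff(left, comp)
  }
  comps
}

# channel-wise two-sample t statistics between pseudovalue matrices,
# then cluster mass after the min-neighbour pruning rule
cluster_mass <- function(pv_post, pv_pre, adj, t_crit, min_neighbors = 2) {
  n1 <- nrow(pv_post); n2 <- nrow(pv_pre)
  m1 <- colMeans(pv_post); m2 <- colMeans(pv_pre)
  v1 <- apply(pv_post, 2, stats::var); v2 <- apply(pv_pre, 2, stats::var)
  tstat <- (m1 - m2) / sqrt(pmax(v1 / n1 + v2 / n2, 1e-300))
  clusters <- list()
  for (sgn in c(1, -1)) {
    supra <- colnames(adj)[sgn * tstat > t_crit]
    # a channel only enters a cluster with >= min_neighbors suprathreshold
    # neighbours (single pass over the original suprathreshold set)
    supra <- supra[vapply(supra, function(ch)
      sum(adj[ch, supra]) >= min_neighbors, TRUE)]
    if (length(supra) == 0) next
    for (comp in components_of(supra, adj)) {
      clusters[[length(clusters) + 1L]] <- list(
        channels = comp, sign = if (sgn > 0) "positive" else "negative",
        stat = sum(tstat[comp]))
    }
  }
  list(tstat = tstat, clusters = clusters)
}

#' Cluster-based permutation test of pre vs. post coherence maps
#'
#' Compares beta-band cortico-muscular coupling between two trial sets at the
#' single-subject level, with trials as the unit of observation. The
#' per-trial quantity is the band-pooled normalized imaginary cross-spectrum
#' (`sum(Im)/sum(|Im|)`, the per-trial analogue of the WPLI's sign
#' consistency; independent across trials, so label permutation is exact
#' under the null). Channels are compared by two-sample t statistics;
#' channels suprathreshold at the cluster-forming level survive only with at
#' least `min_neighbors` suprathreshold neighbours; surviving channels form
#' connected components whose summed t values are the cluster statistics. The null distribution is the maximum
#' absolute cluster statistic over random permutations of the trial condition
#' labels. Positive clusters have post > pre coupling, negative clusters
#' post < pre.
#'
#' @param pre,post `trial_set`s with identical channels.
#' @param adjacency Adjacency matrix (see [neighbors_1020()]).
#' @param n_perm Number of permutations (>= 200).
#' @param alpha Cluster-forming (two-sided) alpha for the channel t tests.
#' @param min_neighbors Minimum suprathreshold neighbours to stay in a
#'   cluster.
#' @param emg_channel,band Passed to [wpli()].
#' @param seed Integer seed for the permutations.
#' @return A `cluster_result`: list with `clusters` (channels, sign, summed
#'   statistic, p-value each), `tstat`, `n_perm`.
#' @export
cluster_permutation <- function(pre, post, adjacency = NULL, n_perm = 1000,
                                alpha = 0.05, min_neighbors = 2,
                                emg_channel = "DELT", band = c(14, 20),
                                seed = 1) {
  if (!identical(pre$eeg_channels, post$eeg_channels)) {
    stop("pre and post trial sets have different channels")
  }
  if (n_perm < 200) stop("use at least 200 permutations")
  if (is.null(adjacency)) {
    adjacency <- neighbors_1020(channels = pre$eeg_channels)
  }
  pv_pre <- wpli_trial_stats(pre, emg_channel, band)
  pv_post <- wpli_trial_stats(post, emg_channel, band)
  # orient each channel by the pooled sign of the imaginary part so that a
  # positive t means stronger phase-locking post; the orientation pools both
  # conditions and is therefore invariant under label permutation
  orient <- sign(colSums(pv_post) + colSums(pv_pre))
  orient[orient == 0] <- 1
  pv_pre <- sweep(pv_pre, 2, orient, "*")
  pv_post <- sweep(pv_post, 2, orient, "*")
  n1 <- nrow(pv_post); n2 <- nrow(pv_pre)
  t_crit <- stats::qt(1 - alpha / 2, df = n1 + n2 - 2)

  obs <- cluster_mass(pv_post, pv_pre, adjacency, t_crit, min_neighbors)
  all_pv <- rbind(pv_post, pv_pre)
  set.seed(as.integer(seed))
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    lab <- sample.int(n1 + n2, n1)
    cm <- cluster_mass(all_pv[lab, , drop = FALSE],
                       all_pv[-lab, , drop = FALSE],
                       adjacency, t_crit, min_neighbors)
    null_max[b] <- if (length(cm$clusters))
      max(vapply(cm$clusters, function(cl) abs(cl$stat), 0)) else 0
  }
  clusters <- lapply(obs$clusters, function(cl) {
    cl$p <- (1 + sum(null_max >= abs(cl$stat))) / (1 + n_perm)
    cl
  })
  structure(list(clusters = clusters, tstat = obs$tstat, n_perm = n_perm,
                 alpha = alpha, null_max = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%d permutations)\n", x$n_perm))
  if (!length(x$clusters)) {
    cat("  no clusters\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf("  %s cluster {%s}: stat %.2f, p = %.4f\n", cl$sign,
                  paste(cl$channels, collapse = ", "), cl$stat, cl$p))
    }
  }
  invisible(x)
}
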