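#' Synthetic SSVEP/SSMVEP session configuration
#'
#' Describes the signal model of the simulator: per-trial multichannel EEG in
#' which, after a visual-pathway latency, sinusoidal components appear at a
#' chosen set of harmonics of the target stimulation frequency (index 0.5 is
#' the subharmonic evoked by half-rate periodic motion of pattern-reversal
#' hybrids; 1 the fundamental; 2, 3, ... the harmonics), scaled by a
#' posterior-gradient channel gain and embedded in 1/f^alpha background
#' noise. Before the latency the recording is noise only.
#'
#' The amplitude defaults emulate the qualitative spectral structure of
#' occipital SSVEP recordings: a dominant fundamental, decaying higher
#' harmonics, and — in `include_subharmonic` (PRS-hybrid) mode — a
#' subharmonic peak of roughly half the fundamental amplitude. FS mode
#' (`include_subharmonic = FALSE`) carries no subharmonic energy.
#'
#' @param frequencies Candidate stimulation frequencies in Hz (default
#'   `c(6, 6.67, 7.5, 10)`, the classic 60 Hz-monitor-compatible set).
#' @param component_amplitudes Named numeric vector mapping harmonic index
#'   (as character: `"0.5"`, `"1"`, ...) to amplitude in arbitrary
#'   microvolt-scale units.
#' @param include_subharmonic Keep the `"0.5"` component? (`TRUE` models a
#'   PRS hybrid with periodic motion, `FALSE` a plain flicker stimulus.)
#' @param noise_alpha Spectral exponent of the 1/f^alpha background
#'   (default 1, classic pink EEG background).
#' @param noise_sigma Noise standard deviation per channel (same units as the
#'   amplitudes). Ignored when `snr_db` is given.
#' @param snr_db Optional signal-to-noise ratio in dB, defined as summed
#'   component power over noise power in the 1-54 Hz band at the
#'   highest-gain (Oz-equivalent) channel; overrides `noise_sigma`.
#' @param latency_s Visual latency before the evoked components start
#'   (default [SSVEP_LATENCY_S]).
#' @param channel_gains Per-channel multiplicative gains (default: an
#'   8-channel posterior gradient peaking at the Oz-equivalent channel).
#' @param phases Optional named numeric vector of per-component phases in
#'   radians; `NULL` (default) randomizes phases per trial.
#' @param fs Sampling rate in Hz (default 256).
#' @param trial_s Stimulation time per trial in seconds (default 5).
#' @param gap_s Noise-only gap before each trial, emulating the cue period
#'   (default 3).
#' @param n_trials_per_class Trials per candidate frequency (default 5).
#' @param seed Integer seed for [generate_session()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(frequencies = c(6, 6.67, 7.5, 10),
                              component_amplitudes = c("0.5" = 0.5, "1" = 1,
                                                       "2" = 0.6, "3" = 0.3,
                                                       "4" = 0.15, "5" = 0.1),
                              include_subharmonic = TRUE,
                              noise_alpha = 1,
                              noise_sigma = 1,
                              snr_db = NULL,
                              latency_s = SSVEP_LATENCY_S,
                              channel_gains = c(O1 = 0.8, Oz = 1, O2 = 0.8,
                                                PO7 = 0.5, PO3 = 0.6,
                                                POz = 0.7, PO4 = 0.6,
                                                PO8 = 0.5),
                              phases = NULL,
                              fs = 256, trial_s = 5, gap_s = 3,
                              n_trials_per_class = 5L, seed = 1L) {
  stopifnot(length(frequencies) >= 2L, all(frequencies > 0),
            all(component_amplitudes >= 0), noise_alpha >= 0,
            noise_sigma >= 0, latency_s >= 0, fs > 0, trial_s > latency_s,
            gap_s >= 0, n_trials_per_class >= 1L)
  if (!include_subharmonic)
    component_amplitudes <- component_amplitudes[names(component_amplitudes) != "0.5"]
  h <- as.numeric(names(component_amplitudes))
  if (anyNA(h)) stop("component_amplitudes must be named by harmonic index")
  if (max(h) * max(frequencies) >= fs / 2)
    stop("a configured component lies at or above the Nyquist frequency")
  structure(list(frequencies = sort(frequencies),
                 component_amplitudes = component_amplitudes,
                 include_subharmonic = include_subharmonic,
                 noise_alpha = noise_alpha, noise_sigma = noise_sigma,
                 snr_db = snr_db, latency_s = latency_s,
                 channel_gains = channel_gains, phases = phases,
                 fs = fs, trial_s = trial_s, gap_s = gap_s,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> f = {%s} Hz, %d x %d trials of %g s",
                     " at %g Hz, %s mode, alpha = %g\n"),
              paste(x$frequencies, collapse = ", "), x$n_trials_per_class,
              length(x$frequencies), x$trial_s, x$fs,
              if (x$include_subharmonic) "PRS-hybrid" else "FS",
              x$noise_alpha))
  invisible(x)
}

#' 1/f^alpha (pink) noise
#'
#' Gaussian noise spectrally shaped to a power spectral density proportional
#' to `1/f^alpha`, generated by scaling the DFT of white Gaussian noise and
#' normalized to unit variance before applying `sigma`. `alpha = 0` gives
#' white noise; `alpha = 1` the canonical pink EEG background.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (>= 0).
#' @param sigma Standard deviation of the output.
#' @return Numeric vector of length `n`. Uses the current RNG state.
#' @export
pink_noise <- function(n, alpha = 1, sigma = 1) {
  stopifnot(n >= 2L, alpha >= 0, sigma >= 0)
  w <- stats::rnorm(n)
  if (alpha == 0 || sigma == 0) return(sigma * w)
  sp <- stats::fft(w)
  k <- 0:(n - 1L)
  km <- pmin(k, n - k)                  # mirrored frequency index
  shape <- 1 / pmax(km, 1L)^(alpha / 2)
  shape[1] <- 0                         # drop DC: EEG is AC-coupled here
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x <- x / stats::sd(x)
  sigma * x
}

# fraction of the variance of pink_noise(alpha) lying in [band] Hz,
# from the analytic spectral shape (used to convert SNR into sigma)
.pink_band_fraction <- function(n, fs, alpha, band) {
  freqs <- (seq_len(n - 1L)) * fs / n          # positive bins incl. mirror
  fmirror <- pmin(freqs, fs - freqs)
  p <- 1 / pmax(fmirror, fs / n)^alpha
  inband <- fmirror >= band[1] & fmirror <= band[2]
  sum(p[inband]) / sum(p)
}

.sim_sigma <- function(cfg) {
  if (is.null(cfg$snr_db)) return(cfg$noise_sigma)
  g_oz <- max(cfg$channel_gains)
  sig_power <- sum((cfg$component_amplitudes * g_oz)^2 / 2)
  n <- round(cfg$trial_s * cfg$fs)
  frac <- .pink_band_fraction(n, cfg$fs, cfg$noise_alpha, c(1, 54))
  noise_band_power <- sig_power / 10^(cfg$snr_db / 10)
  sqrt(noise_band_power / frac)
}

#' Simulate one trial
#'
#' Channels x samples matrix for one trial: from `latency_s` onward, the sum
#' over configured components `h` of
#' `amplitude_h * gain_c * sin(2 * pi * h * f * (t - latency) + phase_h)`,
#' plus independent per-channel 1/f^alpha noise throughout. Phases are drawn
#' once per call from the current RNG state unless fixed in the config.
#'
#' @param cfg A [simulation_config()].
#' @param target_f Target stimulation frequency (must be in
#'   `cfg$frequencies`).
#' @return Channels x samples numeric matrix (row names = channel names).
#' @export
generate_trial <- function(cfg, target_f) {
  stopifnot(inherits(cfg, "simulation_config"),
            target_f %in% cfg$frequencies)
  n <- round(cfg$trial_s * cfg$fs)
  t <- (seq_len(n) - 1L) / cfg$fs
  h <- as.numeric(names(cfg$component_amplitudes))
  phases <- if (is.null(cfg$phases))
    stats::runif(length(h), 0, 2 * pi)
  else cfg$phases[names(cfg$component_amplitudes)]
  active <- t >= cfg$latency_s
  s <- numeric(n)
  for (i in seq_along(h))
    s[active] <- s[active] + cfg$component_amplitudes[i] *
      sin(2 * pi * h[i] * target_f * (t[active] - cfg$latency_s) + phases[i])
  sigma <- .sim_sigma(cfg)
  nc <- length(cfg$channel_gains)
  out <- matrix(0, nc, n)
  for (c in seq_len(nc))
    out[c, ] <- cfg$channel_gains[c] * s +
      if (sigma > 0) pink_noise(n, cfg$noise_alpha, sigma) else 0
  rownames(out) <- names(cfg$channel_gains)
  out
}

#' Simulate a full session
#'
#' Balanced trials (`n_trials_per_class` per candidate frequency) in seeded
#' random order, separated by noise-only gaps of `gap_s` seconds emulating
#' the visual cue period, concatenated into one continuous
#' [eeg_recording()] whose event table holds the trial onsets and target
#' labels.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `simulated_session`: list with `recording`
#'   (an `eeg_recording`), `truth` (per-trial target frequencies in
#'   presentation order) and `config`.
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  labels <- sample(rep(cfg$frequencies, each = cfg$n_trials_per_class))
  n_trial <- round(cfg$trial_s * cfg$fs)
  n_gap <- round(cfg$gap_s * cfg$fs)
  nc <- length(cfg$channel_gains)
  sigma <- .sim_sigma(cfg)
  blocks <- vector("list", 2L * length(labels))
  onsets <- integer(length(labels))
  pos <- 0L
  for (i in seq_along(labels)) {
    gap <- matrix(0, nc, n_gap)
    if (sigma > 0 && n_gap > 0)
      for (c in seq_len(nc)) gap[c, ] <- pink_noise(n_gap, cfg$noise_alpha, sigma)
    blocks[[2L * i - 1L]] <- gap
    pos <- pos + n_gap
    onsets[i] <- pos
    blocks[[2L * i]] <- generate_trial(cfg, labels[i])
    pos <- pos + n_trial
  }
  rec <- eeg_recording(do.call(cbind, blocks), cfg$fs,
                       names(cfg$channel_gains),
                       data.frame(onset_sample = onsets, target_hz = labels))
  structure(list(recording = rec, truth = labels, config = cfg),
            class = "simulated_session")
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("<simulated_session> %d trials over %d classes, %.1f s of data\n",
              length(x$truth), length(unique(x$truth)),
              ncol(x$recording$data) / x$recording$fs))
  invisible(x)
}

#' Estimate component amplitudes from one epoch
#'
#' Single-channel DFT amplitude estimate at each requested harmonic of `f`:
#' `2 * |X(k)| / N` at the bin nearest `h * f`, mirroring how SSVEP component
#' amplitudes are read off an amplitude spectrum. If a requested frequency
#' does not coincide with a DFT bin (mismatch beyond 1% of the bin width), a
#' resolution warning is raised, since spectral leakage then biases the
#' estimate low; use windows covering an integer number of periods of `f/2`
#' to avoid it.
#'
#' @param epoch An [eeg_epoch()] or channels x samples matrix.
#' @param f Stimulation frequency in Hz.
#' @param harmonics Harmonic indices to estimate (default
#'   `c(0.5, 1, 2, 3, 4, 5)`).
#' @param channel Channel name or index to use (default `"Oz"` if present,
#'   else the first channel).
#' @param fs Sampling rate (only needed for a bare matrix).
#' @return Named numeric vector of amplitude estimates, names = harmonic
#'   indices.
#' @export
estimate_component_amplitudes <- function(epoch, f,
                                          harmonics = c(0.5, 1, 2, 3, 4, 5),
                                          channel = NULL, fs = NULL) {
  fs <- .epoch_fs(epoch, fs)
  X <- .epoch_matrix(epoch)
  if (is.null(channel))
    channel <- if ("Oz" %in% rownames(X)) "Oz" else 1L
  x <- X[channel, ]
  n <- length(x)
  spec <- abs(stats::fft(x)) * 2 / n
  bin_hz <- fs / n
  amps <- vapply(harmonics, function(h) {
    fh <- h * f
    k <- round(fh / bin_hz)
    if (abs(fh - k * bin_hz) > bin_hz / 100)
      warning(sprintf("component at %g Hz falls between DFT bins (width %g Hz)",
                      fh, bin_hz), call. = FALSE)
    spec[k + 1L]
  }, numeric(1))
  names(amps) <- as.character(harmonics)
  amps
}
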