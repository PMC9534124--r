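#' Multichannel EEG recording
#'
#' A continuous multichannel recording with its sampling rate, channel names
#' and an event table of task onsets. The canonical occipito-parietal montage
#' for SSVEP work is O1, Oz, O2, PO7, PO3, POz, PO4, PO8, but any channel set
#' is accepted.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param events Data frame with columns `onset_sample` (0-based sample index
#'   of the task onset) and `target_hz` (target stimulation frequency label).
#'   May have zero rows.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, events = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), nrow(data) >= 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  if (is.null(events))
    events <- data.frame(onset_sample = integer(0), target_hz = numeric(0))
  stopifnot(is.data.frame(events),
            all(c("onset_sample", "target_hz") %in% names(events)))
  if (nrow(events) > 0 &&
      (any(events$onset_sample < 0) || any(events$onset_sample >= ncol(data))))
    stop("event onsets must lie within the recording")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples at %g Hz (%.2f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' One analysis epoch
#'
#' A windowed multichannel segment of an [eeg_recording()] with its target
#' frequency label. Constructed by [epoch_extract()].
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds; `ncol(data)` equals
#'   `round(window_s * fs)`.
#' @param target_hz Target frequency label (may be `NA`).
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, window_s, target_hz = NA_real_) {
  stopifnot(is.matrix(data), fs > 0, window_s > 0,
            ncol(data) == round(window_s * fs))
  structure(list(data = data, fs = fs, window_s = window_s,
                 target_hz = target_hz),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples at %g Hz (w = %g s), target %s Hz\n",
              nrow(x$data), ncol(x$data), x$fs, x$window_s,
              format(x$target_hz)))
  invisible(x)
}

#' Downsample a recording by an integer factor
#'
#' Anti-alias filters and decimates each channel (zero-phase Chebyshev
#' decimation via [signal::decimate()]) and rescales the event onsets. The
#' original rate must be an integer multiple of the target rate (e.g. a
#' 2048 Hz acquisition decimated to 256 Hz, factor 8).
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz.
#' @return A new `eeg_recording` at `target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"), target_fs > 0)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop("sampling rate must be an integer multiple of target_fs")
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  out <- t(apply(rec$data, 1L, function(x) signal::decimate(x, q)))
  ev <- rec$events
  ev$onset_sample <- as.integer(round(ev$onset_sample / q))
  eeg_recording(out, target_fs, rec$channel_names, ev)
}

#' Zero-phase Butterworth bandpass
#'
#' Applies a Butterworth bandpass forward and backward ([signal::filtfilt()])
#' to every channel, so the output has no phase delay. The default 2-54 Hz
#' band with design order 6 is the standard SSVEP preprocessing band: it keeps
#' the stimulation fundamentals and their first five harmonics while removing
#' slow drift and line-noise-adjacent content.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Cutoff frequencies in Hz (defaults 2 and 54).
#' @param order Butterworth design order (default 6; the forward-backward pass
#'   doubles the effective magnitude roll-off).
#' @return A filtered `eeg_recording` (same rate, same events).
#' @export
eeg_bandpass <- function(rec, low = 2, high = 54, order = 6) {
  stopifnot(inherits(rec, "eeg_recording"), low > 0, high > low)
  if (high >= rec$fs / 2)
    stop("high cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  eeg_recording(out, rec$fs, rec$channel_names, rec$events)
}

#' Default visual-pathway latency (seconds)
#'
#' The epoching window is shifted by this latency relative to the task onset,
#' to account for the conduction delay of the visual pathway. 0.135 s is the
#' value commonly used for SSVEP decoding on LCD setups; other hardware may
#' warrant a different value, so every function taking a latency accepts an
#' override.
#' @export
SSVEP_LATENCY_S <- 0.135

#' Extract latency-shifted epochs
#'
#' For each event, cuts the half-open window starting `latency_s` after the
#' task onset: start index `round(onset_sample + latency_s * fs)` (0-based),
#' length `round(window_s * fs)` samples. Epochs that would run past the end
#' of the recording raise an error rather than being silently padded.
#'
#' @param rec An [eeg_recording()] with at least one event.
#' @param window_s Window length `w` in seconds.
#' @param latency_s Visual latency shift (default [SSVEP_LATENCY_S]).
#' @return A list of [eeg_epoch()] objects, one per event, labels carried
#'   from the event table.
#' @export
epoch_extract <- function(rec, window_s, latency_s = SSVEP_LATENCY_S) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0, latency_s >= 0)
  if (nrow(rec$events) == 0L) stop("recording has no events to epoch")
  n_s <- as.integer(round(window_s * rec$fs))
  lapply(seq_len(nrow(rec$events)), function(i) {
    onset <- rec$events$onset_sample[i]
    start <- as.integer(round(onset + latency_s * rec$fs))  # 0-based
    if (start + n_s > ncol(rec$data))
      stop(sprintf("epoch %d (samples %d-%d) exceeds the recording length %d",
                   i, start, start + n_s - 1L, ncol(rec$data)))
    eeg_epoch(rec$data[, (start + 1L):(start + n_s), drop = FALSE],
              rec$fs, window_s, rec$events$target_hz[i])
  })
}

#' Write / read the plain-text fixture format
#'
#' A recording is stored as two files sharing a path prefix: `<prefix>.tsv`
#' (tab-separated, samples in rows, one column per channel) and
#' `<prefix>.json` (sidecar with `fs`, `channel_names` and the event table of
#' 0-based `onset_sample` and `target_hz`).
#'
#' @param rec An [eeg_recording()].
#' @param prefix Path prefix (without extension).
#' @return `write_eeg_fixture()` returns `prefix` invisibly;
#'   `read_eeg_fixture()` returns an `eeg_recording`.
#' @export
write_eeg_fixture <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$channel_names
  utils::write.table(m, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- list(fs = rec$fs, channel_names = as.list(rec$channel_names),
               events = lapply(seq_len(nrow(rec$events)), function(i)
                 list(onset_sample = rec$events$onset_sample[i],
                      target_hz = rec$events$target_hz[i])))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_eeg_fixture
#' @export
read_eeg_fixture <- function(prefix) {
  m <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t",
                                   header = TRUE, check.names = FALSE))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ev <- side$events
  if (is.null(ev) || length(ev) == 0L)
    ev <- data.frame(onset_sample = integer(0), target_hz = numeric(0))
  ev <- as.data.frame(ev)
  eeg_recording(t(m), side$fs, unlist(side$channel_names), ev)
}
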