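#' Wolpaw information transfer rate
#'
#' `ITR = (60 / T) * (log2(N) + p * log2(p) + (1 - p) * log2((1 - p) / (N - 1)))`
#' in bits per minute, with the conventions `0 * log2(0) = 0` (so `p = 1`
#' gives `(60 / T) * log2(N)` and chance level `p = 1/N` gives 0). For
#' `p < 1/N` the formula is returned as computed (it can be positive there);
#' consumers that care can flag that regime via [itr_below_chance()].
#'
#' @param p Classification accuracy fraction in `[0, 1]`.
#' @param n_classes Number of classes `N` (>= 2).
#' @param window_s Selection time `T` in seconds (> 0).
#' @return ITR in bits per minute (vectorized over `p`).
#' @examples
#' itr(1, 4, 1)    # 120
#' itr(0.25, 4, 2) # 0 (chance level for 4 classes)
#' @export
itr <- function(p, n_classes, window_s) {
  stopifnot(n_classes >= 2, window_s > 0)
  if (any(p < 0 | p > 1)) stop("accuracy p must lie in [0, 1]")
  plog <- function(q) ifelse(q > 0, q * log2(q), 0)
  bits <- log2(n_classes) + plog(p) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_classes - 1)), 0)
  60 / window_s * bits
}

#' @rdname itr
#' @export
itr_below_chance <- function(p, n_classes) p < 1 / n_classes

#' Classification accuracy
#'
#' @param predictions,truths Equal-length vectors of predicted and true
#'   labels.
#' @return Fraction of matches.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) == 0L || length(predictions) != length(truths))
    stop("predictions and truths must be non-empty and of equal length")
  mean(predictions == truths)
}

#' Wilson binomial confidence interval
#'
#' Score interval for a binomial proportion, used to report sampling
#' uncertainty of simulated accuracies.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# classify every epoch of a list with one method; returns predictions
.classify_epochs <- function(epochs, frequencies, cfg) {
  vapply(epochs, function(ep)
    classify_epoch(ep, frequencies, cfg)$predicted, numeric(1))
}

#' Accuracy/ITR sweep over window sizes and methods
#'
#' Re-epochs a session's recording at each window length, classifies each
#' epoch with each method, and tabulates accuracy and ITR per cell. The
#' recording is bandpass-filtered (2-54 Hz, zero-phase) once up front unless
#' `preprocess = FALSE`.
#'
#' @param session A [generate_session()] result, or an [eeg_recording()]
#'   with a populated event table.
#' @param methods Character vector from `"CCA"`, `"FBCCA"`, `"sFBCCA"`.
#' @param windows Window lengths in seconds (default
#'   `c(1, 1.5, 2, 2.5, 3, 3.5)`).
#' @param cfg A [scoring_config()] supplying all non-method parameters.
#' @param latency_s Epoching latency (default [SSVEP_LATENCY_S]).
#' @param preprocess Apply the standard 2-54 Hz zero-phase bandpass first?
#' @return A data frame of class `sweep_result` with columns `method`,
#'   `window_s`, `accuracy`, `itr_bits_min`, `n_trials`.
#' @export
window_sweep <- function(session, methods = c("CCA", "FBCCA", "sFBCCA"),
                         windows = c(1, 1.5, 2, 2.5, 3, 3.5),
                         cfg = scoring_config(),
                         latency_s = SSVEP_LATENCY_S,
                         preprocess = TRUE) {
  rec <- if (inherits(session, "simulated_session")) session$recording else session
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$events) > 0)
  frequencies <- sort(unique(rec$events$target_hz))
  if (preprocess) rec <- eeg_bandpass(rec)
  rows <- list()
  for (w in windows) {
    epochs <- epoch_extract(rec, w, latency_s)
    truths <- vapply(epochs, `[[`, numeric(1), "target_hz")
    for (m in methods) {
      mcfg <- cfg
      mcfg$method <- m
      pred <- .classify_epochs(epochs, frequencies, mcfg)
      acc <- accuracy(pred, truths)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, window_s = w, accuracy = acc,
        itr_bits_min = itr(acc, length(frequencies), w),
        n_trials = length(truths))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Accuracy sweep over the subharmonic index m_sub
#'
#' Evaluates sFBCCA on the same epochs for a grid of subharmonic indices
#' (hence subharmonic weights `w_sub = m_sub^(-a) + b`), per window length.
#' Mirrors the parameter study used to pick the default `m_sub = 0.5`.
#'
#' @param session As in [window_sweep()].
#' @param m_sub_grid Numeric vector of subharmonic indices (> 0).
#' @param windows Window lengths in seconds.
#' @param cfg A [scoring_config()]; its method is forced to `"sFBCCA"`.
#' @param latency_s Epoching latency.
#' @param preprocess Apply the standard bandpass first?
#' @return A data frame of class `sweep_result` with columns `method`,
#'   `m_sub`, `window_s`, `accuracy`, `itr_bits_min`, `n_trials`.
#' @export
msub_sweep <- function(session, m_sub_grid = c(0.1, 0.25, 0.5, 1, 2, 5),
                       windows = c(1, 2), cfg = scoring_config(),
                       latency_s = SSVEP_LATENCY_S, preprocess = TRUE) {
  stopifnot(all(m_sub_grid > 0))
  rec <- if (inherits(session, "simulated_session")) session$recording else session
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$events) > 0)
  frequencies <- sort(unique(rec$events$target_hz))
  if (preprocess) rec <- eeg_bandpass(rec)
  rows <- list()
  for (w in windows) {
    epochs <- epoch_extract(rec, w, latency_s)
    truths <- vapply(epochs, `[[`, numeric(1), "target_hz")
    for (ms in m_sub_grid) {
      mcfg <- cfg
      mcfg$method <- "sFBCCA"
      mcfg$m_sub <- ms
      mcfg$w_sub <- NULL
      pred <- .classify_epochs(epochs, frequencies, mcfg)
      acc <- accuracy(pred, truths)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "sFBCCA", m_sub = ms, window_s = w, accuracy = acc,
        itr_bits_min = itr(acc, length(frequencies), w),
        n_trials = length(truths))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}
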