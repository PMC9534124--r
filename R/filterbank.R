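#' Scoring configuration for CCA / FBCCA / sFBCCA
#'
#' Bundles every tunable of the filter-bank scoring methods. The defaults are
#' the standard FBCCA settings for SSVEP decoding (`a = 1.25`, `b = 0.25`,
#' five sub-bands with lower edges 4, 8, 12, 16, 20 Hz and a common 52 Hz
#' upper edge) plus the subharmonic extension: a dedicated 1-52 Hz band whose
#' CCA term is weighted by `w_sub = m_sub^(-a) + b` with the subharmonic
#' index `m_sub = 0.5` — placing it at "half a sub-band", so its weight
#' exceeds `w(1)`.
#'
#' @param method `"CCA"`, `"FBCCA"` or `"sFBCCA"`.
#' @param a,b Weight parameters of `w(m) = m^(-a) + b`.
#' @param n_m Number of sub-bands.
#' @param subband_edges List of `c(low, high)` cutoff pairs in Hz, one per
#'   sub-band.
#' @param m_sub Subharmonic index used for `w_sub` (default 0.5).
#' @param sub_band `c(low, high)` cutoffs of the subharmonic band in Hz
#'   (default 1-52).
#' @param n_h Harmonics per reference template (default 5).
#' @param filter_order Butterworth design order of the sub-band filters
#'   (default 6, applied zero-phase).
#' @param w_sub Optional explicit subharmonic weight overriding the
#'   `m_sub^(-a) + b` rule (e.g. `0` to disable the subharmonic term).
#' @param extended_reference_everywhere If `TRUE`, the `m`-indexed sub-band
#'   terms of sFBCCA also use the subharmonic-extended reference; the default
#'   `FALSE` keeps them on the plain harmonic reference so that `w_sub = 0`
#'   reduces sFBCCA to FBCCA exactly.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(method = c("FBCCA", "CCA", "sFBCCA"),
                           a = 1.25, b = 0.25, n_m = 5L,
                           subband_edges = lapply(seq_len(n_m), function(m)
                             c(4 * m, 52)),
                           m_sub = 0.5, sub_band = c(1, 52),
                           n_h = 5L, filter_order = 6L,
                           w_sub = NULL,
                           extended_reference_everywhere = FALSE) {
  method <- match.arg(method)
  stopifnot(length(subband_edges) == n_m, m_sub > 0,
            length(sub_band) == 2L, sub_band[1] < sub_band[2])
  for (e in subband_edges) stopifnot(length(e) == 2L, e[1] < e[2])
  structure(list(method = method, a = a, b = b, n_m = as.integer(n_m),
                 subband_edges = subband_edges, m_sub = m_sub,
                 sub_band = sub_band, n_h = as.integer(n_h),
                 filter_order = as.integer(filter_order), w_sub = w_sub,
                 extended_reference_everywhere = extended_reference_everywhere),
            class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat(sprintf("<scoring_config> %s: a = %g, b = %g, N_m = %d, m_sub = %g, N_h = %d\n",
              x$method, x$a, x$b, x$n_m, x$m_sub, x$n_h))
  invisible(x)
}

#' Sub-band weight w(m) = m^(-a) + b
#'
#' Down-weights higher sub-bands, reflecting the decay of SSVEP harmonic
#' amplitude with frequency; strictly decreasing in `m` for `a > 0`.
#'
#' @param m Sub-band index (>= 1).
#' @param a,b Weight parameters.
#' @return `m^(-a) + b`.
#' @export
subband_weight <- function(m, a = 1.25, b = 0.25) {
  stopifnot(all(m >= 1))
  m^(-a) + b
}

#' Subharmonic weight w_sub = m_sub^(-a) + b
#'
#' The same power law evaluated at the subharmonic index; with `m_sub < 1`
#' the subharmonic term is weighted more heavily than any integer sub-band,
#' emphasizing the motion-evoked half-frequency response.
#'
#' @param m_sub Subharmonic index (> 0), default 0.5.
#' @param a,b Weight parameters.
#' @return `m_sub^(-a) + b`.
#' @export
subharmonic_weight <- function(m_sub = 0.5, a = 1.25, b = 0.25) {
  stopifnot(m_sub > 0)
  m_sub^(-a) + b
}

# zero-phase Butterworth bandpass of a channels x samples matrix
.bandpass_matrix <- function(X, band, fs, order) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  t(apply(X, 1L, function(x) signal::filtfilt(bf, x)))
}

# Filter X once into the N_m sub-bands (+ subharmonic band if asked);
# shared by the scoring functions so FBCCA and sFBCCA use identical filters.
.filterbank_decompose <- function(X, fs, cfg, with_sub = FALSE) {
  bands <- lapply(cfg$subband_edges, function(e)
    .bandpass_matrix(X, e, fs, cfg$filter_order))
  sub <- if (with_sub)
    .bandpass_matrix(X, cfg$sub_band, fs, cfg$filter_order)
  list(bands = bands, sub = sub)
}

.resolve_wsub <- function(cfg) {
  if (is.null(cfg$w_sub)) subharmonic_weight(cfg$m_sub, cfg$a, cfg$b)
  else cfg$w_sub
}

# Weighted sum of squared sub-band CCA coefficients against one reference;
# optionally plus the subharmonic term. `dec` is a .filterbank_decompose()
# result; refs are plain/extended template matrices for the candidate f.
.fb_score <- function(dec, ref_plain, ref_sub, cfg, with_sub) {
  w <- subband_weight(seq_len(cfg$n_m), cfg$a, cfg$b)
  ref_m <- if (with_sub && cfg$extended_reference_everywhere) ref_sub else ref_plain
  s <- 0
  for (m in seq_len(cfg$n_m)) {
    rho <- cca_coefficient(dec$bands[[m]], ref_m)$coefficient
    s <- s + w[m] * rho^2
  }
  if (with_sub) {
    w_sub <- .resolve_wsub(cfg)
    rho_sub <- cca_coefficient(dec$sub, ref_sub)$coefficient
    s <- s + w_sub * rho_sub^2
  }
  s
}

.epoch_matrix <- function(X) if (inherits(X, "eeg_epoch")) X$data else X

.epoch_fs <- function(X, fs) {
  if (inherits(X, "eeg_epoch")) X$fs
  else if (is.null(fs)) stop("fs must be given when X is a bare matrix")
  else fs
}

#' FBCCA score of one epoch for one candidate frequency
#'
#' Decomposes the epoch into the configured sub-bands with zero-phase
#' Butterworth filters, computes the CCA coefficient of each sub-band against
#' the plain harmonic reference for `f`, and returns the weighted sum of the
#' squared coefficients: `sum_m w(m) * rho_m^2`.
#'
#' @param X An [eeg_epoch()] or channels x samples matrix.
#' @param f Candidate stimulation frequency in Hz.
#' @param cfg A [scoring_config()].
#' @param fs Sampling rate (only needed when `X` is a bare matrix).
#' @return The scalar FBCCA score.
#' @export
fbcca_score <- function(X, f, cfg = scoring_config(), fs = NULL) {
  fs <- .epoch_fs(X, fs)
  X <- .epoch_matrix(X)
  .check_epoch_length(X, cfg, fs)
  dec <- .filterbank_decompose(X, fs, cfg, with_sub = FALSE)
  ref <- build_reference(f, cfg$n_h, ncol(X), fs)
  .fb_score(dec, ref, NULL, cfg, with_sub = FALSE)
}

#' sFBCCA score of one epoch for one candidate frequency
#'
#' The FBCCA score plus a dedicated subharmonic term: the epoch is also
#' filtered to the subharmonic band (1-52 Hz by default) and scored with CCA
#' against the subharmonic-extended reference; that squared coefficient
#' enters with weight `w_sub`. With `w_sub = 0` the result equals
#' [fbcca_score()] exactly.
#'
#' @inheritParams fbcca_score
#' @return The scalar sFBCCA score.
#' @export
sfbcca_score <- function(X, f, cfg = scoring_config(method = "sFBCCA"),
                         fs = NULL) {
  fs <- .epoch_fs(X, fs)
  X <- .epoch_matrix(X)
  .check_epoch_length(X, cfg, fs)
  dec <- .filterbank_decompose(X, fs, cfg, with_sub = TRUE)
  ref_plain <- build_reference(f, cfg$n_h, ncol(X), fs)
  ref_sub <- build_reference(f, cfg$n_h, ncol(X), fs,
                             include_subharmonic = TRUE)
  .fb_score(dec, ref_plain, ref_sub, cfg, with_sub = TRUE)
}

# warn (not error) on epochs much shorter than the slowest filter settles in;
# time constant taken as 1/(2*pi*lowest_edge)
.check_epoch_length <- function(X, cfg, fs) {
  lowest <- min(vapply(cfg$subband_edges, `[`, numeric(1), 1L), cfg$sub_band[1])
  if (ncol(X) < 3 * fs / (2 * pi * lowest))
    warning("epoch is shorter than 3 time constants of the lowest sub-band filter",
            call. = FALSE)
  invisible(NULL)
}

#' Classify one epoch by CCA, FBCCA or sFBCCA
#'
#' Scores the epoch for every candidate frequency with the configured method
#' and returns the argmax (ties broken toward the lowest frequency). The
#' sub-band decomposition is computed once and shared across candidates.
#'
#' @param X An [eeg_epoch()] or channels x samples matrix.
#' @param frequencies Candidate stimulation frequencies in Hz.
#' @param cfg A [scoring_config()]; `cfg$method` selects the algorithm.
#' @param fs Sampling rate (only needed when `X` is a bare matrix).
#' @return List with `predicted` (Hz) and `scores` (named numeric vector).
#' @export
classify_epoch <- function(X, frequencies, cfg = scoring_config(), fs = NULL) {
  stopifnot(inherits(cfg, "scoring_config"), length(frequencies) >= 1L)
  fs <- .epoch_fs(X, fs)
  X <- .epoch_matrix(X)
  frequencies <- sort(frequencies)
  if (cfg$method == "CCA") {
    refs <- reference_set(frequencies, cfg$n_h, ncol(X), fs)
    return(classify_cca(X, refs))
  }
  with_sub <- cfg$method == "sFBCCA"
  .check_epoch_length(X, cfg, fs)
  dec <- .filterbank_decompose(X, fs, cfg, with_sub = with_sub)
  scores <- vapply(frequencies, function(f) {
    ref_plain <- build_reference(f, cfg$n_h, ncol(X), fs)
    ref_sub <- if (with_sub)
      build_reference(f, cfg$n_h, ncol(X), fs, include_subharmonic = TRUE)
    .fb_score(dec, ref_plain, ref_sub, cfg, with_sub = with_sub)
  }, numeric(1))
  names(scores) <- as.character(frequencies)
  list(predicted = .argmax_lowest(frequencies, scores), scores = scores)
}
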