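#' Sine/cosine reference template for one candidate frequency
#'
#' Builds the harmonic reference matrix used for CCA-based SSVEP detection:
#' sin/cos pairs at the fundamental and its harmonics `h = 1, ..., N_h`,
#' evaluated on the grid `n = 1/fs, 2/fs, ..., N_s/fs` with zero initial
#' phase. With `include_subharmonic = TRUE` the matrix is extended by a
#' leading sin/cos pair at the subharmonic `f/2` — i.e. `sin(pi f n)` and
#' `cos(pi f n)` — so that responses evoked by half-rate periodic motion
#' (SSMVEP of a pattern-reversal hybrid) contribute to the canonical
#' correlation.
#'
#' @param f Candidate stimulation frequency in Hz.
#' @param n_h Number of harmonics (default 5).
#' @param n_s Number of samples.
#' @param fs Sampling rate in Hz.
#' @param include_subharmonic Prepend the `f/2` sin/cos pair?
#' @return A numeric matrix with `2 * n_h` rows (`+2` with the subharmonic)
#'   and `n_s` columns. Row order: subharmonic sin, subharmonic cos (if
#'   included), then sin/cos for each harmonic in increasing order.
#' @export
build_reference <- function(f, n_h = 5L, n_s, fs, include_subharmonic = FALSE) {
  stopifnot(f > 0, n_h >= 1L, n_s >= 2L * (n_h + 1L), fs > 0)
  if (n_h * f >= fs / 2)
    stop("highest harmonic is at or above the Nyquist frequency")
  n <- seq_len(n_s) / fs
  hs <- seq_len(n_h)
  if (include_subharmonic) hs <- c(0.5, hs)
  out <- matrix(0, nrow = 2L * length(hs), ncol = n_s)
  for (i in seq_along(hs)) {
    w <- 2 * pi * hs[i] * f * n
    out[2L * i - 1L, ] <- sin(w)
    out[2L * i, ] <- cos(w)
  }
  rownames(out) <- as.vector(rbind(paste0("sin_", hs, "f"),
                                   paste0("cos_", hs, "f")))
  out
}

#' Reference templates for a candidate frequency set
#'
#' @param frequencies Candidate stimulation frequencies in Hz.
#' @param n_h Harmonics per template (default 5).
#' @param n_s Samples per template.
#' @param fs Sampling rate in Hz.
#' @param include_subharmonic Extend each template with its `f/2` pair?
#' @return An object of class `reference_set`: list with the (ascending
#'   sorted) `frequencies` and a named list `matrices` of templates.
#' @export
reference_set <- function(frequencies, n_h = 5L, n_s, fs,
                          include_subharmonic = FALSE) {
  stopifnot(length(frequencies) >= 1L, !anyDuplicated(frequencies))
  frequencies <- sort(frequencies)
  mats <- lapply(frequencies, build_reference, n_h = n_h, n_s = n_s, fs = fs,
                 include_subharmonic = include_subharmonic)
  names(mats) <- as.character(frequencies)
  structure(list(frequencies = frequencies, n_h = n_h, fs = fs, n_s = n_s,
                 include_subharmonic = include_subharmonic, matrices = mats),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> f = {%s} Hz, N_h = %d%s, %d samples at %g Hz\n",
              paste(x$frequencies, collapse = ", "), x$n_h,
              if (x$include_subharmonic) " + subharmonic" else "",
              x$n_s, x$fs))
  invisible(x)
}

#' Largest canonical correlation between two multichannel signals
#'
#' Finds weight vectors `w_x`, `w_y` maximizing the Pearson correlation
#' between the linear combinations `t(X) %*% w_x` and `t(Y) %*% w_y`; the
#' maximized correlation is the CCA coefficient used as the SSVEP detection
#' score. Computed by orthonormalizing the centered row spaces (SVD with a
#' relative rank tolerance) and taking the largest singular value of their
#' cross-projection, which is numerically stable even for rank-deficient
#' inputs such as a noiseless single-source epoch.
#'
#' @param X Channels x samples numeric matrix (or an [eeg_epoch()]).
#' @param Y Template x samples numeric matrix with the same number of columns.
#' @param tol Relative singular-value tolerance for rank truncation.
#' @return An object of class `cca_result`: list with `coefficient` (in
#'   `[0, 1]`) and the weight vectors `w_x`, `w_y`.
#' @export
cca_coefficient <- function(X, Y, tol = 1e-10) {
  if (inherits(X, "eeg_epoch")) X <- X$data
  stopifnot(is.matrix(X), is.matrix(Y), ncol(X) == ncol(Y))
  if (ncol(X) <= nrow(X) + nrow(Y))
    warning("sample count is small relative to the combined dimension")
  ox <- .orth_rows(X, tol)
  oy <- .orth_rows(Y, tol)
  sv <- svd(crossprod(ox$basis, oy$basis))
  rho <- min(max(sv$d[1L], 0), 1)
  structure(list(coefficient = rho,
                 w_x = ox$back %*% sv$u[, 1L],
                 w_y = oy$back %*% sv$v[, 1L]),
            class = "cca_result")
}

# Orthonormal basis (columns) of the centered row space of M, plus the map
# from basis coordinates back to row weights.
.orth_rows <- function(M, tol) {
  Mc <- t(M - rowMeans(M))              # samples x channels, centered
  sv <- svd(Mc)
  r <- sum(sv$d > tol * sv$d[1L])
  if (r == 0L || sv$d[1L] == 0) stop("degenerate input: zero variance")
  list(basis = sv$u[, seq_len(r), drop = FALSE],
       back = sv$v[, seq_len(r), drop = FALSE] %*%
         diag(1 / sv$d[seq_len(r)], r))
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> rho = %.6f\n", x$coefficient))
  invisible(x)
}

#' Plain CCA frequency classification
#'
#' Scores an epoch against every template of a [reference_set()] and returns
#' the frequency with the largest CCA coefficient (ties broken toward the
#' lowest frequency).
#'
#' @param X Channels x samples matrix or [eeg_epoch()].
#' @param refs A [reference_set()].
#' @return List with `predicted` (Hz) and `scores` (named numeric vector of
#'   coefficients, one per candidate frequency).
#' @export
classify_cca <- function(X, refs) {
  stopifnot(inherits(refs, "reference_set"))
  if (inherits(X, "eeg_epoch")) X <- X$data
  scores <- vapply(refs$matrices, function(Y)
    cca_coefficient(X, Y)$coefficient, numeric(1))
  names(scores) <- as.character(refs$frequencies)
  list(predicted = .argmax_lowest(refs$frequencies, scores), scores = scores)
}

# argmax with deterministic lowest-frequency tie-breaking (frequencies must
# be sorted ascending)
.argmax_lowest <- function(frequencies, scores) {
  frequencies[which.max(scores)]
}
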