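#' Hybrid visual stimulus specification
#'
#' Describes one of the hybrid SSVEP/SSMVEP visual stimuli: a base stimulus
#' (luminance flicker, `"FS"`, or pattern reversal, `"PRS"`) combined with a
#' periodic size modulation (`"none"`, `"square"`, `"triangular"` or
#' `"sine"`). The nominal stimulation frequency counts full on/off cycles per
#' second for FS and pattern reversals per second for PRS; the size modulation
#' of a PRS hybrid therefore runs at half the nominal frequency (the
#' subharmonic).
#'
#' @param base_kind `"FS"` (flickering stimulus) or `"PRS"` (pattern-reversal
#'   stimulus).
#' @param motion_waveform One of `"none"`, `"square"`, `"triangular"`,
#'   `"sine"`: the temporal waveform of the size modulation.
#' @param stim_frequency_hz Nominal stimulation frequency in Hz. Must be below
#'   half the refresh rate.
#' @param refresh_rate_hz Monitor refresh rate in Hz (default 60).
#' @param modulation_ratio Size-modulation depth relative to the base size,
#'   in (0, 1) (default 0.33: the radius oscillates between 0.67 and 1.33).
#' @param base_size_deg Base stimulus size in degrees of visual angle
#'   (default 5.7).
#'
#' @return An object of class `stimulus_spec`.
#' @seealso [motion_frequency()], [render_frame_table()], [enumerate_stimuli()]
#' @examples
#' stimulus_spec("PRS", "square", 6)
#' @export
stimulus_spec <- function(base_kind = c("FS", "PRS"),
                          motion_waveform = c("none", "square", "triangular", "sine"),
                          stim_frequency_hz,
                          refresh_rate_hz = 60,
                          modulation_ratio = 0.33,
                          base_size_deg = 5.7) {
  base_kind <- match.arg(base_kind)
  motion_waveform <- match.arg(motion_waveform)
  stopifnot(is.numeric(stim_frequency_hz), length(stim_frequency_hz) == 1L,
            stim_frequency_hz > 0,
            is.numeric(refresh_rate_hz), refresh_rate_hz > 0,
            is.numeric(base_size_deg), base_size_deg > 0)
  if (stim_frequency_hz >= refresh_rate_hz / 2)
    stop("stim_frequency_hz must be below half the refresh rate")
  if (!(modulation_ratio > 0 && modulation_ratio < 1))
    stop("modulation_ratio must lie in (0, 1)")
  structure(
    list(base_kind = base_kind,
         motion_waveform = motion_waveform,
         stim_frequency_hz = stim_frequency_hz,
         refresh_rate_hz = refresh_rate_hz,
         modulation_ratio = modulation_ratio,
         base_size_deg = base_size_deg),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s-%s at %g Hz (refresh %g Hz, r = %g)\n",
              x$base_kind,
              paste0(toupper(substring(x$motion_waveform, 1, 1)),
                     substring(x$motion_waveform, 2)),
              x$stim_frequency_hz, x$refresh_rate_hz, x$modulation_ratio))
  invisible(x)
}

#' Motion frequency of a hybrid stimulus
#'
#' The size modulation of an FS hybrid runs at the nominal stimulation
#' frequency; for a PRS hybrid it runs at half of it, so that the motion
#' appears as a subharmonic of the reversal rate in the evoked response.
#'
#' @param spec A [stimulus_spec()].
#' @return Motion frequency in Hz.
#' @examples
#' motion_frequency(stimulus_spec("PRS", "sine", 6)) # 3 Hz
#' @export
motion_frequency <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$base_kind == "FS") spec$stim_frequency_hz else spec$stim_frequency_hz / 2
}

#' Relative size profile of the periodic motion
#'
#' Evaluates the relative stimulus radius (base size = 1) at times `t` for a
#' given motion waveform. All waveforms are periodic with period `1/f_m` and
#' bounded by `1 - r` and `1 + r`:
#' \describe{
#'   \item{none}{constant 1 (no size change).}
#'   \item{square}{alternates between `1 + r` (first half period, starting
#'     enlarged at `t = 0`) and `1 - r`.}
#'   \item{triangular}{starts at `1 - r`, rises linearly to `1 + r` at half
#'     period, then falls back.}
#'   \item{sine}{`1 + r * sin(2 * pi * f_m * t)` (base size at `t = 0`).}
#' }
#'
#' @param waveform `"none"`, `"square"`, `"triangular"` or `"sine"`.
#' @param f_m Motion frequency in Hz.
#' @param r Modulation ratio in (0, 1).
#' @param t Numeric vector of times in seconds (`t >= 0`).
#' @return Numeric vector of relative radii, same length as `t`.
#' @export
size_profile <- function(waveform, f_m, r, t) {
  stopifnot(is.numeric(t), all(t >= 0), f_m > 0, r > 0, r < 1)
  switch(waveform,
    none = rep(1, length(t)),
    square = ifelse(floor(2 * f_m * t) %% 2 == 0, 1 + r, 1 - r),
    triangular = {
      u <- (f_m * t) %% 1
      ifelse(u < 0.5, 1 - r + 4 * r * u, 1 + r - 4 * r * (u - 0.5))
    },
    sine = 1 + r * sin(2 * pi * f_m * t),
    stop("unknown motion waveform: ", waveform)
  )
}

#' Binary flicker / pattern state of a stimulus
#'
#' The on/off (FS) or pattern (PRS) state at times `t`, under the left-closed
#' convention `state = parity(floor(rate * t))`. An FS at `f` Hz completes a
#' full on/off cycle every `1/f` s, so its state toggles `2 f` times per
#' second; a PRS at nominal `f` reversals per second toggles `f` times per
#' second (full pattern period `2/f` s).
#'
#' @param spec A [stimulus_spec()].
#' @param t Numeric vector of times in seconds (`t >= 0`).
#' @return Integer vector of 0/1 states.
#' @export
binary_state <- function(spec, t) {
  stopifnot(inherits(spec, "stimulus_spec"), is.numeric(t), all(t >= 0))
  rate <- if (spec$base_kind == "FS") 2 * spec$stim_frequency_hz else spec$stim_frequency_hz
  as.integer(floor(rate * t) %% 2 == 0)
}

#' Frame-quantized stimulus profile
#'
#' Samples the binary state and the relative size profile on the monitor's
#' frame grid `t = k / refresh_rate_hz`, `k = 0, ..., floor(duration *
#' refresh) - 1`, as the stimulus would actually be presented on an LCD. The
#' size profile is driven at [motion_frequency()] of the spec.
#'
#' @param spec A [stimulus_spec()].
#' @param duration Duration in seconds (> 0).
#' @return A data frame of class `frame_sequence` with columns `frame`
#'   (0-based index), `time_s`, `state` (0/1) and `relative_radius`.
#' @examples
#' ft <- render_frame_table(stimulus_spec("FS", "none", 6), 1)
#' nrow(ft) # 60 frames at the default 60 Hz refresh
#' @export
render_frame_table <- function(spec, duration) {
  stopifnot(inherits(spec, "stimulus_spec"), duration > 0)
  n <- floor(duration * spec$refresh_rate_hz)
  k <- seq_len(n) - 1L
  t <- k / spec$refresh_rate_hz
  radius <- if (spec$motion_waveform == "none") rep(1, n) else
    size_profile(spec$motion_waveform, motion_frequency(spec),
                 spec$modulation_ratio, t)
  out <- data.frame(frame = k, time_s = t,
                    state = binary_state(spec, t),
                    relative_radius = radius)
  class(out) <- c("frame_sequence", "data.frame")
  out
}

#' Enumerate the eight hybrid stimuli at one frequency
#'
#' The cross product of the two base kinds and the four motion waveforms, in
#' fixed order: FS first, waveforms in the order none, square, triangular,
#' sine.
#'
#' @param frequency Nominal stimulation frequency in Hz.
#' @param refresh_rate_hz Monitor refresh rate (default 60).
#' @return A list of 8 [stimulus_spec()] objects.
#' @export
enumerate_stimuli <- function(frequency, refresh_rate_hz = 60) {
  kinds <- c("FS", "PRS")
  waves <- c("none", "square", "triangular", "sine")
  out <- list()
  for (k in kinds) for (w in waves)
    out[[length(out) + 1L]] <- stimulus_spec(k, w, frequency,
                                             refresh_rate_hz = refresh_rate_hz)
  out
}
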