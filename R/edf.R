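#' Read an EDF or BDF recording
#'
#' Minimal reader for European Data Format (EDF, 16-bit) and BioSemi Data
#' Format (BDF, 24-bit) continuous recordings. All ordinary signal channels
#' sharing the modal sampling rate are returned, scaled to physical units via
#' the per-channel digital/physical calibration in the header; annotation and
#' status channels ("EDF Annotations", "BDF Annotations", "Status") are
#' dropped. The event table of the returned [eeg_recording()] is empty —
#' trigger decoding is hardware-specific, so attach events yourself.
#'
#' @param path Path to a `.edf` or `.bdf` file.
#' @param channels Optional character vector of channel labels to keep.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- readBin(con, "raw", 8L)
  is_bdf <- magic[1] == as.raw(255L) &&
    rawToChar(magic[2:8]) == "BIOSEMI"
  afield <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  afield(80); afield(80); afield(8); afield(8)           # patient/recording/date/time
  afield(8); afield(44)                                  # header bytes / reserved
  n_rec <- as.integer(afield(8))
  rec_dur <- as.numeric(afield(8))
  ns <- as.integer(afield(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF/BDF header")

  sfield <- function(n) vapply(seq_len(ns), function(i) {
    trimws(rawToChar(readBin(con, "raw", n)))
  }, character(1))
  labels <- sfield(16)
  sfield(80); sfield(8)                                  # transducer / phys dim
  phys_min <- as.numeric(sfield(8)); phys_max <- as.numeric(sfield(8))
  dig_min <- as.numeric(sfield(8));  dig_max <- as.numeric(sfield(8))
  sfield(80)                                             # prefilter
  spr <- as.integer(sfield(8))                           # samples per record
  sfield(32)                                             # reserved

  bps <- if (is_bdf) 3L else 2L
  keep <- !labels %in% c("EDF Annotations", "BDF Annotations", "Status")
  keep <- keep & spr == max(spr[keep])
  if (!is.null(channels)) keep <- keep & labels %in% channels
  if (!any(keep)) stop("no matching signal channels in ", path)

  raw_rec <- vector("list", n_rec)
  sizes <- spr * bps
  for (r in seq_len(n_rec)) {
    chans <- vector("list", ns)
    for (s in seq_len(ns)) {
      bytes <- readBin(con, "raw", sizes[s])
      if (length(bytes) < sizes[s]) stop("truncated data record in ", path)
      if (!keep[s]) next
      chans[[s]] <- if (is_bdf) int24_le(bytes) else
        readBin(bytes, "integer", spr[s], size = 2L, signed = TRUE,
                endian = "little")
    }
    raw_rec[[r]] <- chans
  }

  idx <- which(keep)
  data <- do.call(rbind, lapply(idx, function(s) {
    dig <- unlist(lapply(raw_rec, `[[`, s), use.names = FALSE)
    (dig - dig_min[s]) * (phys_max[s] - phys_min[s]) /
      (dig_max[s] - dig_min[s]) + phys_min[s]
  }))
  eeg_recording(data, fs = spr[idx[1]] / rec_dur, channel_names = labels[idx])
}

# decode little-endian signed 24-bit integers packed in a raw vector
int24_le <- function(bytes) {
  b <- as.integer(bytes)
  n <- length(b) / 3L
  i <- 3L * (seq_len(n) - 1L)
  v <- b[i + 1L] + 256L * b[i + 2L] + 65536L * b[i + 3L]
  ifelse(v >= 8388608L, v - 16777216L, v)
}
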