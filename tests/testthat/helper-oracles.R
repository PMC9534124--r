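# Independent oracles and fixture builders shared across the suite.

# Largest canonical correlation via the generalized eigenvalue route:
# rho^2 is the largest eigenvalue of Cxx^-1 Cxy Cyy^-1 Cyx on centered data.
# Deliberately a different algorithm from the package's SVD-projection path.
cca_oracle <- function(X, Y, ridge = 0) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  n <- ncol(X)
  Cxx <- tcrossprod(Xc) / n + ridge * diag(nrow(X))
  Cyy <- tcrossprod(Yc) / n + ridge * diag(nrow(Y))
  Cxy <- tcrossprod(Xc, Yc) / n
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  sqrt(max(0, max(Re(eigen(M, only.values = TRUE)$values))))
}

# A multichannel sinusoidal epoch: sum of components (harmonic index h of f)
# with given amplitudes/phases, scaled per channel by gains.
sin_epoch <- function(f, fs, n_s, amplitudes, gains = c(1, 0.8, 0.6),
                      phases = rep(0, length(amplitudes))) {
  t <- seq_len(n_s) / fs
  h <- as.numeric(names(amplitudes))
  s <- numeric(n_s)
  for (i in seq_along(h))
    s <- s + amplitudes[i] * sin(2 * pi * h[i] * f * t + phases[i])
  out <- outer(gains, s)
  rownames(out) <- paste0("ch", seq_along(gains))
  out
}

# Write a minimal EDF (16-bit) or BDF (24-bit) file directly as raw bytes,
# independently of the package reader. `data` is channels x samples in
# physical units; one data record holding everything.
write_edf_bytes <- function(path, data, fs, labels, bdf = FALSE,
                            phys_min = -1000, phys_max = 1000) {
  ns <- nrow(data)
  spr <- ncol(data)
  dig_min <- if (bdf) -8388608 else -32768
  dig_max <- if (bdf) 8388607 else 32767
  pad <- function(x, n) {
    s <- sprintf(paste0("%-", n, "s"), as.character(x))
    charToRaw(substr(s, 1, n))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (bdf) {
    writeBin(as.raw(255), con)
    writeBin(pad("BIOSEMI", 7), con)
  } else {
    writeBin(pad("0", 8), con)
  }
  writeBin(pad("patient", 80), con)
  writeBin(pad("recording", 80), con)
  writeBin(pad("01.01.20", 8), con)
  writeBin(pad("00.00.00", 8), con)
  writeBin(pad(256 + 256 * ns, 8), con)
  writeBin(pad("", 44), con)
  writeBin(pad(1, 8), con)                       # one record
  writeBin(pad(format(spr / fs), 8), con)        # record duration
  writeBin(pad(ns, 4), con)
  for (l in labels) writeBin(pad(l, 16), con)
  for (i in 1:ns) writeBin(pad("transducer", 80), con)
  for (i in 1:ns) writeBin(pad("uV", 8), con)
  for (i in 1:ns) writeBin(pad(phys_min, 8), con)
  for (i in 1:ns) writeBin(pad(phys_max, 8), con)
  for (i in 1:ns) writeBin(pad(dig_min, 8), con)
  for (i in 1:ns) writeBin(pad(dig_max, 8), con)
  for (i in 1:ns) writeBin(pad("none", 80), con)
  for (i in 1:ns) writeBin(pad(spr, 8), con)
  for (i in 1:ns) writeBin(pad("", 32), con)
  for (i in 1:ns) {
    dig <- round((data[i, ] - phys_min) * (dig_max - dig_min) /
                   (phys_max - phys_min) + dig_min)
    if (bdf) {
      for (v in dig) {
        u <- if (v < 0) v + 16777216 else v
        writeBin(as.raw(c(u %% 256, (u %/% 256) %% 256, u %/% 65536)), con)
      }
    } else {
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
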