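make_rec <- function(fs = 256, dur = 8, freqs = c(10), nch = 2,
                     events = data.frame(onset_sample = 0L, target_hz = 10)) {
  t <- (seq_len(dur * fs) - 1) / fs
  x <- rowSums(sapply(freqs, function(f) sin(2 * pi * f * t)))
  eeg_recording(matrix(rep(x, each = nch), nch, byrow = FALSE), fs,
                events = events)
}

test_that("downsampling decimates, preserves in-band amplitude, rescales events", {
  fs0 <- 2048
  t <- (seq_len(8 * fs0) - 1) / fs0
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 7.5 * t)),
                       fs0,
                       events = data.frame(onset_sample = 4096L, target_hz = 10))
  out <- downsample(rec, 256)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), 8 * 256)
  expect_equal(out$events$onset_sample, 512L)
  # amplitude of the 10 Hz sinusoid preserved within 1% (interior samples)
  mid <- 500:1500
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.01)
  # the decimated signal still is a 10 Hz sinusoid: correlate with the ideal
  td <- (mid - 1) / 256
  expect_gt(abs(cor(out$data[1, mid], sin(2 * pi * 10 * td))), 0.999)
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("bandpass is zero-phase and attenuates out-of-band content", {
  fs <- 256
  t <- (seq_len(8 * fs) - 1) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t),
                             sin(2 * pi * 0.5 * t),
                             sin(2 * pi * 100 * t)), fs,
                       events = data.frame(onset_sample = 0L, target_hz = 10))
  out <- eeg_bandpass(rec)
  mid <- 500:1500
  # in-band sinusoid: unchanged amplitude, cross-correlation peak at lag 0
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.02)
  cc <- ccf(out$data[1, mid], rec$data[1, mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 0.5 Hz drift and a 100 Hz tone both attenuated by > 20 dB
  expect_lt(20 * log10(max(abs(out$data[2, mid]))), -20)
  expect_lt(20 * log10(max(abs(out$data[3, mid]))), -20)
  expect_error(eeg_bandpass(rec, high = 130), "Nyquist")
})

test_that("stimulation-band sinusoids survive the whole chain unscathed", {
  fs0 <- 2048
  t <- (seq_len(8 * fs0) - 1) / fs0
  for (f in c(6, 6.67, 7.5, 10)) {
    rec <- eeg_recording(matrix(sin(2 * pi * f * t), 1), fs0,
                         events = data.frame(onset_sample = 0L, target_hz = f))
    out <- eeg_bandpass(downsample(rec, 256))
    mid <- 500:1500
    expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.02)
    td <- (mid - 1) / 256
    # zero phase shift: least-squares in-phase amplitude stays ~1
    s <- sin(2 * pi * f * td)
    expect_equal(mean(out$data[1, mid] * s) / mean(s * s), 1, tolerance = 0.03)
  }
})

test_that("epoching uses the latency-shifted half-open window", {
  fs <- 256
  rec <- make_rec(fs = fs, dur = 8,
                  events = data.frame(onset_sample = c(0L, 512L),
                                      target_hz = c(10, 7.5)))
  eps <- epoch_extract(rec, 1)
  expect_length(eps, 2)
  expect_equal(ncol(eps[[1]]$data), 256)
  expect_equal(eps[[1]]$target_hz, 10)
  expect_equal(eps[[2]]$target_hz, 7.5)
  # start index round(0.135 * 256) = 35 (0-based): sample 36 in R indexing
  expect_identical(eps[[1]]$data[1, 1], rec$data[1, 36])
  expect_identical(eps[[2]]$data[1, 1], rec$data[1, 512 + 36])
  expect_equal(ncol(epoch_extract(rec, 3.5)[[1]]$data), 896)
  # no silent padding
  late <- eeg_recording(rec$data, fs,
                        events = data.frame(onset_sample = ncol(rec$data) - 10L,
                                            target_hz = 10))
  expect_error(epoch_extract(late, 1), "exceeds")
  # epoching is exact and repeatable
  expect_identical(epoch_extract(rec, 2)[[1]]$data,
                   epoch_extract(rec, 2)[[1]]$data)
})

test_that("the fixture format round-trips recordings exactly enough", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(3 * 100), 3), 256,
                       channel_names = c("Oz", "O1", "O2"),
                       events = data.frame(onset_sample = c(5L, 40L),
                                           target_hz = c(6, 10)))
  prefix <- file.path(tempdir(), "fix")
  write_eeg_fixture(rec, prefix)
  back <- read_eeg_fixture(prefix)
  expect_equal(back$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$events$onset_sample, rec$events$onset_sample)
  expect_equal(back$events$target_hz, rec$events$target_hz)
})

test_that("EDF and BDF files written byte-by-byte are read back correctly", {
  set.seed(2)
  fs <- 128
  t <- (seq_len(fs) - 1) / fs
  data <- rbind(Oz = 50 * sin(2 * pi * 10 * t), POz = rnorm(fs, sd = 20))
  for (bdf in c(FALSE, TRUE)) {
    path <- file.path(tempdir(), if (bdf) "t.bdf" else "t.edf")
    write_edf_bytes(path, data, fs, rownames(data), bdf = bdf)
    rec <- read_edf(path)
    expect_equal(rec$fs, fs)
    expect_equal(rec$channel_names, c("Oz", "POz"))
    # quantization: 2000/65536 ~ 0.031 uV for EDF, finer for BDF
    tol <- if (bdf) 1e-3 else 0.05
    expect_equal(rec$data, data, tolerance = tol, ignore_attr = TRUE)
  }
  # channel selection
  path <- file.path(tempdir(), "t.edf")
  expect_equal(read_edf(path, channels = "Oz")$channel_names, "Oz")
})

test_that("recording construction validates its invariants", {
  expect_error(eeg_recording(matrix(0, 2, 10), 256,
                             events = data.frame(onset_sample = 20L,
                                                 target_hz = 6)),
               "within the recording")
  expect_error(eeg_recording(matrix(0, 2, 10), -1), "fs")
})
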