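test_that("pink noise has the requested scale and a decaying spectrum", {
  set.seed(31)
  x <- pink_noise(4096, alpha = 1, sigma = 2)
  expect_equal(sd(x), 2, tolerance = 1e-9)
  expect_equal(mean(x), 0, tolerance = 0.2)
  # low-frequency band power exceeds an equal-width high band
  sp <- abs(fft(x))^2
  expect_gt(sum(sp[2:200]), 2 * sum(sp[1001:1199]))
  # alpha = 0 is white: the two bands are comparable
  w <- pink_noise(4096, alpha = 0, sigma = 1)
  spw <- abs(fft(w))^2
  expect_lt(sum(spw[2:200]) / sum(spw[1001:1199]), 2)
})

test_that("trials carry the configured components after the latency", {
  cfg <- simulation_config(noise_sigma = 0,
                           phases = c("0.5" = 0, "1" = 0, "2" = 0,
                                      "3" = 0, "4" = 0, "5" = 0))
  tr <- generate_trial(cfg, 10)
  expect_equal(dim(tr), c(8, 5 * 256))
  expect_equal(rownames(tr), c("O1", "Oz", "O2", "PO7", "PO3", "POz",
                               "PO4", "PO8"))
  # noise-free and zero-phase: silent before the latency
  n_lat <- floor(0.135 * 256)
  expect_true(all(tr[, 1:n_lat] == 0))
  expect_gt(max(abs(tr[, (n_lat + 2):100])), 0)
  # channel gains scale the common source exactly
  expect_equal(tr["O1", ], 0.8 * tr["Oz", ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a pure-fundamental noise-free trial is a textbook template signal", {
  cfg <- simulation_config(component_amplitudes = c("1" = 1),
                           noise_sigma = 0, latency_s = 0,
                           phases = c("1" = pi / 2))
  tr <- generate_trial(cfg, 10)
  # spectral peak at 10 Hz only
  amps <- estimate_component_amplitudes(tr, 10, c(0.5, 1, 2, 3), fs = 256)
  expect_equal(unname(amps[["1"]]), 1, tolerance = 0.01)
  expect_lt(max(amps[c("0.5", "2", "3")]), 0.01)
  # CCA against the 10 Hz template is ~1
  ref <- build_reference(10, 5, ncol(tr), 256)
  expect_equal(cca_coefficient(tr, ref)$coefficient, 1, tolerance = 1e-6)
})

test_that("trial and session generation are deterministic under a seed", {
  cfg <- simulation_config(snr_db = 5, seed = 99L)
  set.seed(1); t1 <- generate_trial(cfg, 6)
  set.seed(1); t2 <- generate_trial(cfg, 6)
  expect_identical(t1, t2)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$recording$events, s2$recording$events)
  expect_identical(s1$truth, s2$truth)
})

test_that("sessions are balanced with gap-separated onsets", {
  cfg <- simulation_config(snr_db = 10, seed = 3L)
  ses <- generate_session(cfg)
  expect_length(ses$truth, 20)
  expect_equal(unname(table(ses$truth)), rep(5L, 4), ignore_attr = TRUE)
  ev <- ses$recording$events
  expect_equal(nrow(ev), 20)
  expect_equal(ev$target_hz, ses$truth)
  # onsets separated by at least trial + gap
  expect_true(all(diff(ev$onset_sample) >= (5 + 3) * 256))
  expect_equal(ev$onset_sample[1], 3 * 256)
  big <- simulation_config(n_trials_per_class = 50L, snr_db = 10)
  expect_length(generate_session(big)$truth, 200)
})

test_that("component amplitudes are recovered within 10% at SNR >= 10 dB", {
  cfg <- simulation_config(component_amplitudes = c("0.5" = 0.5, "1" = 1,
                                                    "2" = 0.6),
                           snr_db = 10, seed = 4L)
  set.seed(4)
  for (f in c(6, 7.5, 10)) {
    tr <- generate_trial(cfg, f)
    # analyse the post-latency signal so the DFT sees the full components
    n0 <- floor(0.135 * 256)
    # 4 s: an integer number of periods of f/2 for all of 6, 7.5, 10 Hz
    seg <- tr[, (n0 + 1):(n0 + 4 * 256)]
    got <- suppressWarnings(
      estimate_component_amplitudes(seg, f, c(0.5, 1, 2), fs = 256))
    expect_equal(unname(got), c(0.5, 1, 0.6), tolerance = 0.1)
  }
})

test_that("recovered amplitudes are monotone in the configured amplitudes", {
  set.seed(5)
  levels <- c(0.3, 0.6, 1.2)
  got <- sapply(levels, function(a) {
    cfg <- simulation_config(component_amplitudes = c("1" = a),
                             include_subharmonic = FALSE,
                             snr_db = 15)
    tr <- generate_trial(cfg, 6)
    n0 <- floor(0.135 * 256)
    unname(estimate_component_amplitudes(tr[, (n0 + 1):(n0 + 4.5 * 256)], 6,
                                         1, fs = 256))
  })
  expect_true(all(diff(got) > 0))
})

test_that("FS mode drops the subharmonic and its energy", {
  cfg <- simulation_config(include_subharmonic = FALSE, noise_sigma = 0,
                           phases = c("1" = 0, "2" = 0, "3" = 0, "4" = 0,
                                      "5" = 0))
  expect_false("0.5" %in% names(cfg$component_amplitudes))
  tr <- generate_trial(cfg, 10)
  amps <- estimate_component_amplitudes(tr, 10, c(0.5, 1), fs = 256)
  expect_lt(unname(amps[["0.5"]]), 0.02)
  expect_gt(unname(amps[["1"]]), 0.9)
})

test_that("off-bin components trigger a resolution warning", {
  cfg <- simulation_config(noise_sigma = 0, phases = c("0.5" = 0, "1" = 0,
                                                       "2" = 0, "3" = 0,
                                                       "4" = 0, "5" = 0))
  tr <- generate_trial(cfg, 6.67)
  # 1 s window: 1 Hz bins; 6.67 Hz and 3.335 Hz both fall between bins
  expect_warning(estimate_component_amplitudes(tr[, 1:256], 6.67, 0.5,
                                               fs = 256), "bins")
})

test_that("nonsensical configurations are rejected", {
  expect_error(simulation_config(component_amplitudes = c("15" = 1)),
               "Nyquist")
  expect_error(simulation_config(frequencies = 6), "frequencies")
  expect_error(simulation_config(noise_alpha = -1), "alpha")
})
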