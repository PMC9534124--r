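# sfbcca

Training-free frequency decoding for SSVEP brain-computer interfaces, with
a subharmonic-extended filter-bank CCA for hybrid motion stimuli.

## The problem

A steady-state visual evoked potential (SSVEP) BCI presents several visual
stimuli, each flickering or pattern-reversing at its own frequency, and
infers which one the user is looking at from occipital EEG. Hybrid stimuli
add a periodic *size modulation* (none, square, triangular or sine waveform)
to a conventional flickering stimulus (FS) or pattern-reversal stimulus
(PRS). For PRS hybrids the motion runs at half the reversal rate, so the
evoked response carries energy not only at the stimulation frequency `f` and
its harmonics but also at the *subharmonic* `f/2` — information that
standard decoders ignore.

This package is for BCI researchers and engineers who want to

- generate the frame-quantized temporal profiles of the eight hybrid
  stimuli (2 base kinds x 4 motion waveforms),
- decode multichannel EEG with CCA, filter-bank CCA (FBCCA) or the
  subharmonic-extended FBCCA (sFBCCA),
- and test the whole stack on synthetic recordings with a realistic
  spectral structure, without EEG hardware.

## The decoders

**CCA.** For an epoch `X` (channels x samples) and a harmonic reference
`Y_f = [sin(2πfn); cos(2πfn); …; sin(2πN_h f n); cos(2πN_h f n)]`,
the detection score is the largest canonical correlation
`ρ_f = max_{w_x, w_y} corr(Xᵀw_x, Y_fᵀw_y)`, and the decoded frequency is
`argmax_f ρ_f`.

**FBCCA.** The epoch is decomposed into `N_m = 5` sub-bands (4–52, 8–52,
12–52, 16–52, 20–52 Hz, zero-phase Butterworth) and the score is the
weighted sum of squared sub-band coefficients

```
ρ_f = Σ_{m=1}^{N_m} w(m) · (ρ_f^m)²,   w(m) = m^(-a) + b,   a = 1.25, b = 0.25.
```

**sFBCCA.** One extra term scores the 1–52 Hz band against the
subharmonic-extended reference (adds `sin(πfn)`, `cos(πfn)` rows):

```
ρ_f = Σ_m w(m) · (ρ_f^m)² + w_sub · (ρ_f^sub)²,   w_sub = m_sub^(-a) + b,
```

with subharmonic index `m_sub = 0.5`, so `w_sub ≈ 2.63` outweighs every
integer sub-band.

Preprocessing follows the standard SSVEP chain: decimation to 256 Hz,
6th-order zero-phase Butterworth bandpass 2–54 Hz, and epoching shifted by
the 0.135 s visual-pathway latency. Performance is summarized by accuracy
and the Wolpaw information transfer rate (bits/min).

## Worked example

```r
library(sfbcca)

# A synthetic PRS-hybrid session: 20 trials (5 per class) at 6, 6.67, 7.5,
# 10 Hz, 0 dB SNR in pink noise, 8 posterior channels.
cfg <- simulation_config(snr_db = 0, n_trials_per_class = 5, seed = 42)
ses <- generate_session(cfg)
ses
#> <simulated_session> 20 trials over 4 classes, 160.0 s of data

rec <- eeg_bandpass(ses$recording)       # zero-phase 2-54 Hz
eps <- epoch_extract(rec, window_s = 1)  # 1 s windows, 0.135 s latency

out <- classify_epoch(eps[[1]], cfg$frequencies,
                      scoring_config(method = "sFBCCA"))
out$scores
#>        6     6.67      7.5       10
#> 2.068195 3.253194 2.785019 4.984683
out$predicted
#> [1] 10
eps[[1]]$target_hz
#> [1] 10
```

The score vector holds one sFBCCA score per candidate frequency; the
decoded frequency is the argmax (here the 10 Hz target, scored well above
the competitors). Sweeping windows and methods over the whole session:

```r
window_sweep(ses, methods = c("FBCCA", "sFBCCA"), windows = c(1, 2))
#>   method window_s accuracy itr_bits_min n_trials
#> 1  FBCCA        1        1          120       20
#> 2 sFBCCA        1        1          120       20
#> 3  FBCCA        2        1           60       20
#> 4 sFBCCA        2        1           60       20
```

At this SNR every 1 s window decodes perfectly (120 bits/min for a perfect
4-class selection per second); lower the SNR (e.g. `snr_db = -12`) to see
the methods separate from the ceiling.

A command-line front end is in `exec/sfbcca` with subcommands `stimgen`,
`simulate`, `classify`, `sweep` and `msub-sweep`.

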