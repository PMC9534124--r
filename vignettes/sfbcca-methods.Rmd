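---
title: "Decoding hybrid SSVEP/SSMVEP stimuli with subharmonic filter-bank CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hybrid SSVEP/SSMVEP stimuli with subharmonic filter-bank CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfbcca)
```

## Background and model

A steady-state visual evoked potential (SSVEP) appears in occipital EEG as
a periodic response phase-locked to a repetitive visual stimulus, with
spectral peaks at the stimulation frequency and its harmonics. Adding a
periodic size modulation to a stimulus additionally evokes a steady-state
*motion* VEP (SSMVEP). The hybrid stimuli modeled here combine a flickering
(FS) or pattern-reversal (PRS) base with a size modulation of waveform
none, square, triangular or sine. Two frequency conventions matter:

- **FS** counts full on/off cycles per second: the state toggles `2f`
  times per second, and its motion runs at the nominal `f`.
- **PRS** counts reversals per second: the state toggles `f` times per
  second (full pattern period `2/f`), and its motion runs at `f/2`.

Because the PRS motion runs at half the reversal rate, its evoked response
carries a **subharmonic** component at `f/2` — absent from FS hybrids —
that a standard decoder never examines. The package implements three
training-free decoders:

1. **CCA**: the largest canonical correlation between the multichannel
   epoch and a sine/cosine reference at harmonics `1 … N_h` of each
   candidate frequency, maximized over spatial/reference weights; decoded
   frequency = argmax.
2. **FBCCA**: the epoch is decomposed into `N_m` sub-bands and the squared
   sub-band coefficients are combined with weights `w(m) = m^(-a) + b`.
3. **sFBCCA**: FBCCA plus one subharmonic term: the epoch filtered to a
   wide low-reaching band (1–52 Hz) is scored against a reference extended
   with `sin(πfn)`, `cos(πfn)` rows, and the squared coefficient enters
   with weight `w_sub = m_sub^(-a) + b`.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| candidate frequencies | 6, 6.67, 7.5, 10 | Hz | the classic 4-class set compatible with a 60 Hz monitor (60/10, 60/9, 60/8, 60/6) |
| `N_h` (harmonics) | 5 | — | standard choice for harmonic references; 5·10 Hz stays below the 54 Hz band edge |
| `a`, `b`, `N_m` | 1.25, 0.25, 5 | — | the established FBCCA weight/bank setting |
| sub-band edges | 4/8/12/16/20–52 | Hz | m-th band starts at the m-th multiple of the lowest fundamental's band |
| `m_sub` | 0.5 | — | indexes the subharmonic "half a band below" band 1, giving `w_sub ≈ 2.63 > w(1) = 1.25` |
| subharmonic band | 1–52 | Hz | must reach below the lowest subharmonic (3 Hz) with margin |
| bandpass | 2–54, order 6, zero-phase | Hz | keeps fundamentals through 5th harmonics; forward–backward Butterworth |
| latency | 0.135 | s | visual-pathway conduction delay; epoch windows start this long after stimulus onset |
| sampling rate | 256 (from 2048) | Hz | decimation by 8 for computational cost; all components lie far below Nyquist |
| modulation ratio | 0.33 | — | relative radius oscillates between 0.67 and 1.33 |

`6.67` is treated as the nominal value 6.67 everywhere (references and
simulator alike), not as 20/3: internal consistency between the generator
and the decoder matters more than monitor-exact timing, and the decoders
only ever compare an epoch with references built under the same
convention.

## Design choices where the design was open

- **Zero-phase "order 6"** is read as *design* order 6 applied
  forward–backward (effective 12th-order magnitude). This is the most
  common reading of zero-phase filter descriptions; `eeg_bandpass(order=)`
  lets you halve it if you prefer the other reading.
- **Which reference do the `m`-indexed terms of sFBCCA use?** The plain
  harmonic reference; only the dedicated subharmonic term uses the extended
  reference. This keeps sFBCCA with `w_sub = 0` *bit-identical* to FBCCA
  (an invariant the tests assert) and isolates the subharmonic information
  in its own term. The alternative — extended references everywhere — is
  available via `scoring_config(extended_reference_everywhere = TRUE)`.
- **Motion phase conventions.** Square motion starts enlarged, triangular
  starts at the minimum, sine starts at the base size; binary state starts
  "on". The steady-state analysis is phase-invariant, so these are fixed
  only to make frame tables reproducible.
- **Tie-breaking** in the argmax is toward the lowest candidate frequency;
  determinism is required and the choice is otherwise arbitrary.
- **CCA numerics**: both inputs are mean-centered (the objective is a
  Pearson correlation); row spaces are orthonormalized by SVD with a
  relative rank tolerance of 1e-10 and the coefficient is the largest
  singular value of the cross-projection. This handles rank-deficient
  epochs (e.g. a noiseless single-source trial, where all channels are
  proportional) without forming ill-conditioned covariance inverses.
  All-zero input is a degenerate-input error.
- **Short epochs** (shorter than three time constants of the slowest
  sub-band filter, with the time constant taken as `1/(2π·f_low)`) trigger
  a warning, not an error: 1 s windows are routine in SSVEP work, and the
  filter transients they carry degrade but do not invalidate the scores.
- **ITR below chance** is returned as the formula computes it (it can be
  positive below `1/N`); `itr_below_chance()` flags the regime instead of
  silently clipping.
- The **subharmonic weight override** `scoring_config(w_sub = )` exists so
  the additive structure of the sFBCCA score can be tested (and the term
  disabled) without distorting the `m`-indexed weights.

## The synthetic-data generator

`generate_trial()` emulates the spectral structure of occipital recordings
under these stimuli: from the 0.135 s latency onward, sinusoids at the
configured harmonic indices of the target frequency (`0.5` = subharmonic,
`1` = fundamental, `2 …` harmonics), scaled by a fixed posterior channel
gain profile (peak at the Oz-equivalent channel), in independent
per-channel `1/f` Gaussian noise; before the latency, noise only.
`generate_session()` concatenates balanced trials (default 5 per class,
matching a 20-trial session of 5 s stimulations) in seeded random order
with noise-only cue gaps.

The default component amplitudes — subharmonic 0.5, fundamental 1.0, then
0.6, 0.3, 0.15, 0.1 — are free parameters chosen once to mirror the
qualitative shape of reported amplitude spectra for PRS hybrids (dominant
fundamental, decaying harmonics, clear subharmonic peak); FS mode simply
drops the subharmonic component. `snr_db` sets the noise scale as summed
component power over 1–54 Hz noise power at the highest-gain channel.

What the generator does **not** model: alpha rhythm and other structured
background, eye-blink/EMG artifacts, inter-subject latency and amplitude
variability, electrode noise correlations, and any nonlinearity of the
visual response. Passing tests on this generator therefore demonstrate
algorithmic correctness (the decoders find the structure the signal model
contains), not clinical performance on real EEG.

On these synthetic sessions FBCCA and sFBCCA perform almost identically:
the subharmonic term is largely redundant with the first sub-band because
the extended reference also contains every harmonic row, and the 1–52 Hz
band admits the heaviest `1/f` noise. The package's directional claim is
therefore modest — adding the subharmonic term does not hurt (and the
tests assert sFBCCA ≥ FBCCA within paired binomial sampling error). A
larger advantage would require real recordings in which the subharmonic
carries discriminative information that the in-band harmonics lack.

## Problem sizes used in the tests

The test-suite study conditions are: 4 classes at {6, 6.67, 7.5, 10} Hz,
8 channels at 256 Hz, 5 s trials, 1 s decoding windows. Noiseless checks
use 20-trial sessions; noise-robustness and the FBCCA/sFBCCA comparison
use 200-trial sessions (50 per class) at SNRs of +5 to −15 dB, with
Wilson/paired-binomial allowances for sampling error at that size. The
CCA implementation is checked against an independent generalized-
eigenvalue solver on 100+ random instances to 1e-8, and against
`stats::cancor` as a second route.

## Known limitations

- EDF/BDF reading covers continuous equal-rate signal channels and drops
  annotation/status channels; trigger decoding is left to the caller.
- The decimator requires integer rate ratios (the intended 2048 → 256 Hz
  path); arbitrary resampling is out of scope.
- Score magnitudes across methods are not comparable (CCA coefficients vs
  weighted sums of squares); only within-method argmax matters.
- `estimate_component_amplitudes()` is a bare DFT-bin reader: it assumes
  the analysis window holds an integer number of component periods and
  warns otherwise rather than interpolating.
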