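Package: sfbcca
Title: Subharmonic Filter-Bank Canonical Correlation Analysis for
    SSVEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Training-free frequency decoding for steady-state visual
    evoked potential (SSVEP) brain-computer interfaces. Implements
    canonical correlation analysis (CCA) against sine/cosine harmonic
    reference templates, filter-bank CCA (FBCCA), and a
    subharmonic-extended FBCCA (sFBCCA) that adds a dedicated
    subharmonic-band term for hybrid stimuli whose periodic motion runs
    at half the pattern-reversal rate. Also provides the temporal
    profiles of eight hybrid visual stimuli (flicker or pattern
    reversal combined with none/square/triangular/sine size modulation),
    a zero-phase preprocessing chain (decimation, Butterworth bandpass,
    latency-shifted epoching), a synthetic multichannel SSVEP/SSMVEP
    simulator with 1/f background noise, EDF/BDF readers, the Wolpaw
    information transfer rate, and sweep drivers for window length and
    subharmonic-weight studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
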