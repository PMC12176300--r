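Package: cyclewave
Title: Spectral Analysis and Phase Mapping of Reproductive Hormone Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Least-squares spectral analysis of irregularly sampled hormone
    time series: a generalized (floating-mean) Lomb-Scargle periodogram with
    permutation-based false alarm probability, sinusoid waveform
    reconstruction, day-to-phase-angle mapping with the pi/2-peak convention,
    and cross-species alignment of named cycle-phase windows. Also provides
    longitudinal immune fold-change statistics (one-sample Wilcoxon
    signed-rank tests against unity with false discovery rate control), a
    significance filter for differential-expression tables, and a seeded
    synthetic-data generator emulating mouse repeat-pseudopregnancy and
    macaque menstrual-cycle sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
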