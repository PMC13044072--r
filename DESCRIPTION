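Package: geobands
Title: Geometric EEG Frequency-Band Schemes and Spectral Band Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs parametric EEG frequency-band schemes in which band
    centers follow an exponential law f_ref * R^n and band boundaries are the
    geometric means of adjacent centers, so that bands tessellate the
    frequency axis with equal log-spacing. Provides the default scheme
    anchored at the 10.5 Hz adult alpha mean with scaling ratio R = 1.7275,
    alpha subdivision at the reference frequency, a classical Titius-Bode
    comparator, data-driven re-anchoring via individual alpha frequency (IAF)
    peak detection on 1/f-detrended spectra, band-power integration of power
    spectral densities, alignment metrics against environmental reference
    modes (Schumann resonances), a spectral-peak geometric-ratio conformity
    estimator, seeded synthetic PSD and time-series generators with Welch
    spectral estimation, CSV/JSON readers and writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
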