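Package: lemnaclock
Title: Circadian Rhythm Quantification and Photoperiodic Flowering Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying circadian rhythms from bioluminescence
    reporter time series and relating them to photoperiodic flowering in
    short-day plants such as duckweed. Implements moving-average detrending
    and moving-SD amplitude normalization, peak detection by local quadratic
    fitting, free-running period estimation by FFT-seeded nonlinear
    least-squares multicomponent cosine fitting with relative amplitude
    error (RAE), critical day-length estimation from flowering assays by the
    50-percent-of-maximum piecewise-linear rule, association statistics
    (Pearson correlation, Deming errors-in-variables regression, pairwise
    Wilcoxon tests with Holm adjustment and compact letter displays), a
    two-parameter external-coincidence gate model linking period to critical
    day length, and a synthetic-data generator emulating an
    entrainment-then-constant-light luminescence protocol so every stage can
    be tested against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    graphics,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
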