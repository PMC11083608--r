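Package: hrvkit
Title: Heart Rate Variability Analysis from ECG and RR Interval Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete heart-rate-variability (HRV) analysis toolkit for
    single-lead ECG recordings and RR-interval tachograms. Provides ECG
    preprocessing (smoothing, baseline removal, zero-phase low-pass),
    Pan-Tompkins QRS detection with adaptive thresholding and search-back,
    normal-to-normal (NN) interval filtering, time-domain and geometric
    indices (SDNN, SDANN, RMSSD, SDNN index, pNN50, HRV triangular index,
    TINN), Welch-periodogram spectral analysis with VLF/LF/HF band powers
    and normalized units, Poincare plot quantification (SD1/SD2),
    recurrence-plot quantification (recurrence rate, determinism,
    laminarity, entropy), delay-embedding diagnostics (average mutual
    information, false nearest neighbors, 3-D attractor export), group
    comparison statistics (Welch t-test, one-way ANOVA, mean squared and
    relative error), and a seeded synthetic cardio-signal generator that
    emulates healthy, extrasystolic-arrhythmia and vasovagal-syncope-like
    rhythms with per-beat ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
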