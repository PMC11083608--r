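---
title: "Methods and design choices in hrvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in hrvkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvkit)
```

`hrvkit` implements the full heart-rate-variability analysis chain —
ECG conditioning, QRS detection, NN-interval construction, and the
time-domain, spectral, Poincaré, recurrence and phase-space families of
HRV measures — together with a synthetic cardio-signal generator that
provides ground truth for every stage. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and what
the package's synthetic validation does and does not demonstrate about
real recordings.

## The signal path

### Preprocessing

`preprocess_ecg()` applies four stages in order: a centered moving average
(`w_avg = 5` samples), DC removal, subtraction of a running-median baseline
estimate (`w_med = 0.6` s), and a zero-phase Butterworth low-pass
(`f_lp = 40` Hz, effective order 4, applied forward–backward). The median
window is the load-bearing choice: at 0.6 s it is longer than any QRS
complex (so the QRS does not leak into the baseline estimate) and shorter
than typical baseline-wander periods (a 0.3 Hz wander is attenuated by
more than 90 %). All stages are symmetric or zero-phase, because every
downstream HRV quantity inherits its accuracy from R-peak *timing*: the
test suite verifies that the full chain moves fiducials by at most one
sample on noise-free synthetic ECG. Each stage can be disabled
independently (`w_avg = 1`, `w_med = NULL`, `f_lp = NULL`).

### QRS detection

`detect_qrs()` is a faithful Pan–Tompkins implementation: 5–15 Hz
band-pass, five-point derivative, pointwise squaring, 150 ms moving-window
integration, then adaptive dual-threshold classification of integrator
peaks with

* a 200 ms refractory period,
* T-wave discrimination inside 360 ms (a candidate whose maximal filtered
  slope is below half the previous QRS slope is classified as a T wave),
* running signal/noise level estimates updated with coefficient 0.125,
* search-back with a halved threshold whenever no beat has been accepted
  within 1.66 × the running average of the last eight RR intervals.

These constants are the ones published with the original algorithm; the
paper trail on modern variants mostly tunes them per database, so all are
exposed as arguments. The final fiducial is the maximum of the *input*
ECG within ±100 ms of the integrator peak; no sub-sample interpolation is
performed, so peak times are quantized to the sampling grid (at 250 Hz
this bounds RR jitter by ±2 samples = 8 ms, and the round-trip test
asserts exactly that bound).

### NN filtering

The study chain analyzes *normal-to-normal* intervals. No acceptance rule
is standardized in the literature we follow, so `nn_filter()` uses a
documented, testable one: an interval is accepted when it lies in
[300, 2000] ms and deviates from the median of the previous five accepted
intervals by at most 20 %. Against generator truth (8–10 % ectopy with
0.6× prematurity and 1.4× compensatory pauses), this rule flags both the
premature beat and its pause with recall ≥ 0.9, and it is idempotent.

## Time-domain and geometric indices

`hrv_time()` follows the conventional (Task Force) definitions: SDNN is
the sample (n−1) standard deviation of all intervals of the record; SDANN
and the SDNN index are the sd of 5-minute segment means and the mean of
5-minute segment sds. Segments are consecutive non-overlapping 300 s
windows on beat time; an interval belongs to the window containing the
beat that opens it, and an incomplete tail is dropped. Both segment
statistics are `NA` with fewer than two complete segments. pNN50 uses the
number of successive differences (n−1) as its denominator and is reported
in percent.

The histogram for the geometric indices uses a bin width of 7.8125 ms
(1/128 s), the standard discretization for HRVTi/TINN. TINN is found by
brute force: over all bin-edge pairs `N < mode < M`, fit the triangle that
is zero outside `[N, M]` and peaks at the mode center with the observed
mode height, minimizing squared error against the bin counts; TINN is
`M − N`. The search is exact on the edge grid, so an independent oracle in
the test suite must agree to machine precision, and a symmetric triangle
spanning nine bins is recovered within one bin width.

## Spectral analysis

The tachogram (interval length against the time of the beat that closes
the interval) is cubic-spline interpolated and resampled at 4 Hz
(`resample_tachogram()`), comfortably above twice the 0.4 Hz upper HF
edge. `welch_psd()` then removes the mean, splits the series into Hamming
windows of `seg_len = 256` samples (64 s at 4 Hz — at least four windows
on a 5-minute record) with 50 % overlap, normalizes each modified
periodogram by the window power `U = (1/M) Σ w(n)²`, and averages. Only
the mean is removed (no polynomial detrend), because the VLF band is
reported and aggressive detrending would corrupt it.

The absolute scale of an averaged, windowed periodogram is
convention-dependent, so the one-sided density is calibrated so that its
trapezoidal integral over the full frequency axis equals the population
variance of the detrended series. Band powers are then trapezoidal
integrals (with interpolated band-edge points) over VLF/LF/HF in ms², and
`lf_nu + hf_nu = 1` holds to rounding error by construction. Consequences
worth knowing: the white-noise Parseval check is exact rather than
approximate, and band powers can never exceed the tachogram variance.

## Poincaré, recurrence and phase space

`hrv_poincare()` uses population (divide-by-n) normalization so that
`SD1 = RMSSD/√2` is an exact identity whenever successive differences have
zero mean (the time-domain module keeps the sample-sd convention; the two
conventions differ at order 1/n). `SD1² + SD2²` equals the summed
population variance of the paired coordinates for any input — a rotation
invariant the tests assert at 10⁻⁶ relative.

`rqa()` excludes the line of identity from every count. REC is the
off-identity recurrent fraction; DET and LAM are the fractions of those
points on diagonal/vertical runs of length ≥ 2 (`l_min = v_min = 2`);
ENTR is the Shannon entropy, in nats, of the diagonal-length distribution.
On a symmetric matrix vertical and horizontal runs coincide, which is why
only vertical runs are scanned. A finite-size subtlety: in a fully
recurrent N×N matrix the two corner points lie on length-1 diagonals, so
DET is 100·(N²−N−2)/(N²−N), not exactly 100. The default threshold is
`epsilon = 0.1 ×` the maximal pairwise embedded distance; a fixed-ms
threshold is also exposed. No Theiler window beyond the identity line is
applied.

`ami()` estimates mutual information from a 16-bin equal-width 2-D
histogram (nats). The optimal delay is the *first local minimum judged
over ±2 lags*: histogram MI estimates of strongly periodic series ripple
at single-lag scale (the binned joint distribution of an exactly periodic
signal is supported on finitely many cells), and a strict three-point rule
can stop on that ripple. The ±2 window is the smallest neighborhood that
suppressed it; if no local minimum exists the global minimum is used, with
a warning. `fnn()` implements the Kennel criteria (`rtol = 15`,
`atol = 2` in units of the series sd) with a Theiler exclusion of τ
samples and a next-nearest fallback for duplicate points *to floating
tolerance* (distances below 10⁻⁸ sd are treated as duplicates — exact
repetitions of a periodic signal differ by rounding, and ratio tests on
rounding-scale distances are meaningless). `m_opt` is the first dimension
with FNN ≤ 1 %; when the curve never crosses the threshold — the expected
outcome for strongly stochastic series with no low-dimensional structure —
the dimension of the curve minimum is reported with a warning, so the
automated pipeline (`hrv_rqa()` with unspecified `m`, `tau`) always
receives finite embedding parameters.

## The synthetic generator

`synth_rr()` draws beats sequentially:

RR(n) = μ(tₙ) + A_rsa·sin(2π f_rsa tₙ) + A_lf·sin(2π f_lf tₙ + φ)
       + A_vlf·sin(2π f_vlf tₙ + ψ) + ε,  ε ~ N(0, σ²)

with per-beat ectopy (prematurity factor, compensatory-pause multiplier on
the following beat) and step changes of μ at configured times. Phases and
all noise flow from a single seed. The shipped cohort defaults are fixed
once:

| cohort | μ (ms) | A_rsa/A_lf/A_vlf (ms) | σ (ms) | ectopy | regime shifts |
|---|---|---|---|---|---|
| healthy | 892 | 20 / 25 / 30 | 15 | 0 | none |
| arrhythmia | 746 | 4 / 6 / 10 | 4 | 8 %, 0.6×, pause 1.4× | none |
| syncope | 654 | 2 / 3 / 6 | 3 | 0 | 600/710/620 ms at 150/300/450 s |

The means are the cohort scales of the study the package accompanies; the
modulation and noise amplitudes were chosen so the healthy spec lands in
the normal short-term-variability range (RMSSD ≈ 25–30 ms) while the
pathological specs reproduce the *direction* of every published contrast
(low RMSSD/SD1, torpedo-shaped Poincaré clouds, elevated recurrence
determinism). The generator admits a closed-form RMSSD
(`expected_rmssd()`): white noise contributes 2σ² to the mean squared
successive difference and each modulation `2A² sin²(π f Δt̄)` — the
parameter-recovery test requires agreement within 10 % at ~2000 beats.

What the generator does *not* emulate: morphological beat classes
(ventricular vs supraventricular ectopy), respiratory non-stationarity,
circadian trends, 1/f-like fractal scaling, and measurement artifacts
other than additive noise. Passing the synthetic validation therefore
demonstrates correctness of the *computations* and sensible behavior of
the *pipeline*, not clinical equivalence on real Holter data; the
published cohort tables come from external recordings and are not
reproduction targets.

`synth_ecg()` exists to exercise detection: one P-QRS-T template (sums of
Gaussians, R amplitude 1 mV) per beat on the sample grid, plus optional
baseline wander, powerline interference and white noise. Truth peaks are
the exact template centers, which is what makes the ±1-sample detection
assertions meaningful.

## Statistics

`compare_groups()` defaults to Welch (unequal-variance) two-sided t-tests
against a reference group, plus classic one-way ANOVA across all groups;
the pooled-variance t-test is available behind `var_equal = TRUE` (with
two groups its p-value coincides with the ANOVA, F = t²). No
multiple-testing correction is applied by default, matching the
presentation style of clinical HRV tables. `relative_error()` compares
series *means* (the device-validation convention when no beat-pairing rule
exists); `mse()` is the plain mean squared difference of paired series.

## Problem sizes and reproducibility

The validation suite runs at deliberately modest sizes chosen to keep the
full check under a few minutes while leaving no estimator in a
small-sample regime where its guarantees would be vacuous: 120 s ECGs
across a 40–180 bpm sweep and ten noise seeds for detection; 5–10-minute
tachograms for the spectral, Poincaré and recurrence cohorts (50 seeds for
the cross-cohort direction checks); series of length ≤ 200 for the exact
O(N²) recurrence oracle; n = 16384 for the delay-estimation demonstration
(the AMI minimum of a sampled sine is shallow, and shorter series let
estimator noise move the argmin by ±2 lags — the test adds 10 % observation
noise because an *exactly* periodic noise-free sine has a degenerate,
plateau-shaped binned-MI curve with no unique quarter-period minimum).
Every stochastic component takes an explicit seed, and `hrv_analyze()`
output is byte-identical across runs with the same input and
configuration.

## Known limitations

* The detector is validated on synthetic morphology only; real ECG with
  pathological QRS shapes, lead inversion or muscle artifact will need
  parameter adjustment (everything is exposed in the function arguments).
* Frequency analysis assumes the tachogram is interpolable — dense ectopy
  violates the spline's assumptions; filter to NN intervals first.
* The recurrence threshold convention (fraction of maximal phase-space
  extent) makes REC comparable across records only under identical
  embedding settings; `hrv_cohort()` therefore fixes `m`, `tau` and the
  epsilon fraction across all records of a comparison.
* ENTR is reported in nats; published tables that use bits differ by a
  factor of log(2).
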