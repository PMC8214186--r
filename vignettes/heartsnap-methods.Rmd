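---
title: "Methods: camera heart rate, field VO2max tests, and their validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: camera heart rate, field VO2max tests, and their validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartsnap)
```

## What this package measures

Cardiorespiratory fitness is summarized by VO2max (maximal oxygen uptake,
mL·kg⁻¹·min⁻¹). Gold-standard measurement needs a metabolic cart and a
supervised maximal treadmill test; field protocols approximate it from a
3-minute step test (VO2max inferred from heart-rate recovery) or a
12-minute run test (VO2max inferred from distance covered). `heartsnap`
implements the signal-processing stack that makes both protocols run on a
smartphone: heart rate from flash-illuminated fingertip video, distance
from privacy-preserving 1 Hz displacement GPS, plus the skin-tone
covariate and the agreement statistics used to validate such measurements.
Everything is testable offline against seeded synthetic data with known
ground truth.

## Camera photoplethysmography heart rate

The phone records no video. Each frame is reduced to the mean pixel
intensity per color channel, giving three time series sampled at a nominal
60 Hz. Blood-volume pulsation under the fingertip modulates these means
quasi-periodically at the heart rate.

The estimator (`hr_timecourse()`) proceeds in four steps:

1. **Uniform resampling** (`resample_uniform()`). Camera timestamps jitter,
   and both zero-phase filtering and autocorrelation assume a uniform
   grid, so channels are linearly interpolated onto one at the nominal
   rate.
2. **Band-pass filtering and mean-centering** (`ppg_preprocess()`). A
   zero-phase (forward-backward) Butterworth band-pass with a 4th-order
   transfer function and pass band 0.6–4.0 Hz. The band covers the
   supported 45–210 bpm range (0.75–3.5 Hz) with margin while removing
   baseline intensity, illumination drift, and high-frequency sensor
   noise. Both edges are configurable (`hr_config()`).
3. **Windowing** (`split_windows()`). Consecutive non-overlapping 10 s
   windows; a 10 s window holds at least 7 beats even at 45 bpm, enough
   for a stable period estimate. Trailing partial windows are discarded.
   Overlap was left out deliberately: it buys temporal resolution at the
   cost of correlated window estimates, which would complicate the
   retention accounting.
4. **Autocorrelation period estimation** (`ppg_acf()`). The biased
   (divide-by-N) sample autocorrelation, normalized so the lag-0 value is
   1, makes every later value a scale-free magnitude bounded by 1.
   Candidate periods are local ACF maxima whose lag lies in the band of
   physiological periods and whose normalized magnitude reaches the
   spurious-peak threshold (default 0.25 of the lag-0 peak). The
   largest-magnitude candidate is the fundamental; heart rate is
   `rate × 60 / lag`.

### Numerical choices in the period search

*Lag bounds.* A period at exactly the edge of the supported range rarely
falls on an integer lag (210 bpm at 60 Hz is 17.14 samples). The search
bounds are therefore rounded *outward* — `floor(rate·60/hr_max)` to
`ceiling(rate·60/hr_min)` — so an edge-rate signal still has its ACF peak
inside the searched window; inward rounding would silently drop signals at
the advertised limits of the estimator.

*Sub-sample refinement.* Integer-lag resolution is coarse where it matters
most: near 210 bpm one lag step changes the estimate by ~12 bpm. The
selected peak's lag is refined by a parabola through the ACF values at the
neighboring lags; with refinement the clean-signal error stays below
0.4 bpm across the whole range (the finite-window taper of the biased ACF
shifts the peak by at most ~0.3 samples, worth under 0.2 bpm). The refined
estimate is clamped into `[hr_min, hr_max]`.

*Degenerate windows.* A constant (flat) window has no defined ACF; it
yields zero candidates, confidence 0, and an invalid flag rather than an
error, so long captures degrade gracefully.

### Confidence score and quality control

The confidence score is the normalized ACF magnitude at the fundamental
lag — a number in [0, 1] that is 0 when no candidate survives and
approaches 1 for a strongly periodic window (`confidence_score()`). An
alternative reading of the score — the ratio of the fundamental peak's
magnitude to the next candidate peak's — is also implemented
(`peak_ratio_score()`), but it is unbounded above and cannot support a
fixed cutoff of 0.5 on a [0, 1] scale, so the bounded normalized-ACF
definition is the default and the ratio is exposed as a clearly named
secondary diagnostic. The two definitions coexist in the package because
the measurement protocol describes the score both ways; the discrepancy is
documented rather than resolved.

Windows with fused confidence below the cutoff (default **0.5**) are
retained in the output but flagged invalid; the retained fraction is the
quality-control summary, and `retention_curve()` reproduces the
retention-vs-cutoff analysis (non-increasing by construction).

### Channel fusion

Red and green channels are estimated independently and fused by taking the
estimate from the channel with the higher confidence. Ties break to green:
hemoglobin absorbs more strongly at green wavelengths, so green typically
carries the stronger pulsatile component. Blue is parsed, simulated, and
optionally estimated, but never fused.

## VO2max estimation

**Step test.** The protocol counts heart beats between 30 and 60 s after
stepping ends (HB3060). From windowed estimates this is the
overlap-weighted mean of valid fused heart rates over
`[test_end + 30, test_end + 60]` times half a minute
(`hb3060_from_windows()`); overlap weighting is needed because 10 s
analysis windows do not align with the 30 s interval. VO2max is then the
affine Milligan (Tecumseh-family) equation

    VO2max = 83.477 − 0.586·HB3060 − 0.404·age − 7.030·sex

with sex coded 0 = male, 1 = female. **Run test.** Cooper's (1968)
equation `VO2max = (d12 − 504.9) / 44.73`, d12 in meters. Both coefficient
sets are configuration objects (`step_coefficients()`,
`run_coefficients()`) carrying a mandatory `source` string, so substituted
equations stay traceable; no coefficient is hard-coded elsewhere.
Plausibility guards warn on HB3060 outside 22.5–105 beats and d12 outside
500–6000 m (the latter catches meters/kilometers mix-ups, which shift the
result by an order of magnitude). VO2max is rounded to one decimal only at
presentation (CLI), never internally.

## GPS distance

Phones record 1 Hz *relative* displacements — planar meters on one
platform, Δlatitude/Δlongitude in degrees plus an absolute anchor on the
other. `reconstruct_path()` rebuilds a planar path: cumulative sums for
the meters dialect; for the degrees dialect the anchor is added back and
coordinates are projected by a local equirectangular projection about the
anchor (R = 6,371,000 m). The projection, rather than repeated haversine,
is used because displacements accumulate in coordinate space first and
runs span a few kilometers at most, where the projection error is well
under 0.1% (the two dialects agree to that tolerance in the tests).
Distance is the Euclidean sum over subsequent points (`distance_raw()`),
and additionally after Savitzky–Golay smoothing of the x and y sequences
(`distance_smoothed()`; default window 9 samples = 9 s, polynomial
order 3). The filter reproduces degree-≤3 trajectories exactly, so
noiseless paths keep their length, while iid GPS jitter — which strictly
inflates the raw sum — is attenuated. Endpoints use the filter's
least-squares endpoint fits (the standard Savitzky–Golay boundary rows)
rather than mirror padding; both reproduce polynomials, and the
least-squares rows are the established implementation in `signal`. Which
of the two estimates the deployed app reported is not documented, so both
are exposed. Per-sample steps above 15 m at 1 Hz (faster than a
world-record sprint) are flagged, not dropped.

## Skin tone: individual typology angle

`compute_ita()` evaluates `arctan((L* − 50) / b*) × 180 / 3.14159` from
spectrocolorimetry CIELAB values. The literal constant 3.14159 is the
default so results match the deployed arithmetic digit-for-digit;
`exact_pi = TRUE` switches to π (the difference is below 0.002° over the
physiological range). For `b* ≤ 0`, possible under instrument noise, the
two-argument arctangent resolves the sign of `L* − 50` toward the ±90°
limits with a warning; `L* = 50, b* = 0` is undefined and errors. The
six-category chain (very light > 55° > light > 41° > intermediate > 28° >
tan > 10° > brown > −30° > dark) is written with strict inequalities on
both sides, leaving boundary values unassigned; the convention here
assigns each boundary to the darker-adjacent class (exactly 55° is
"light"), which keeps `classify_ita()` monotone and is configurable via
the cutoff table.

## Agreement statistics

`lin_ccc()` implements Lin's concordance correlation with population (1/n)
moments, matching the original formulation (a flag switches to n−1);
`bland_altman()` returns bias and `bias ± 1.96·sd` limits of agreement
(sample sd); `percent_error()` uses absolute error by default with a
signed variant; `icc_test_retest()` is the single-measure two-way
random-effects absolute-agreement ICC — ICC(2,1) — computed from the
mean-squares decomposition, with the variant name embedded in every
result because "ICC" alone is ambiguous. The ICC variant used in the
original validation analyses is not documented; ICC(2,1) is the standard
test-retest choice and is reported as this package's choice, not as a
claim about other software. Subjects with missing repeats are dropped
listwise with a warning.

## Synthetic data: what it emulates, what it does not

`simulate_ppg()` drives a phase-continuous oscillator through a heart-rate
profile (constant, or mono-exponential recovery
`hr(t) = asymptote + (start − asymptote)·e^(−t/τ)` — a modeling choice
for ground truth, not an empirical claim), with a configurable harmonic
pulse shape, per-channel gains, baseline drift, additive Gaussian noise,
and an offset into a 0–255-like intensity range. The default pulse carries
a 0.4-amplitude second harmonic because harmonic rejection is the hard
case for ACF period selection — a pure sinusoid would flatter the
estimator. The analytic beat integral provides exact per-window mean heart
rates. `simulate_track()` builds line/circle/waypoint paths at constant
speed with iid Gaussian position jitter, returned in either dialect with
analytic true length. `simulate_agreement_cohort()` draws subject effects
and noise with known variance components, so the implied ICC
(`subject_sd² / (subject_sd² + error_sd²)`) is exact ground truth. All
generators are pure functions of their spec including the seed, and they
restore the caller's RNG state.

What the simulators do *not* model: real PPG morphology (dicrotic notch,
respiratory modulation, motion artifacts), heteroscedastic or colored
sensor noise, skin-tone-dependent optics beyond a crude channel gain, GPS
dropout bursts or autocorrelated multipath error. Passing the synthetic
closed-loop tests therefore demonstrates the algorithms implement their
definitions and are numerically sound — not that field accuracy on real
captures is reproduced. The published cohort-level concordance values
depend on participant data that is not available, and are deliberately
not asserted anywhere in this package.

## Problem sizes and tolerances used in the tests

The test suite runs entirely on synthetic data: 10–60 s captures at
60 Hz, a full 45–210 bpm integer sweep of clean single windows (error
bound 1 bpm), 100 noisy windows for the periodogram-oracle equivalence
check at ~6 dB SNR (unit-amplitude pulse, noise sd 0.35, agreement within
one 0.1 Hz frequency bin — below that SNR the ACF's preference for the
largest peak can pick a subharmonic where a periodogram does not, so the
SNR level is part of the documented property), 200-replicate Monte-Carlo
runs for noise-window rejection and for smoothed-vs-raw distance under
3 m jitter, 720 m/12-minute tracks, and a 500-subject cohort for ICC
recovery (analytic value 0.9, tolerance 0.03). Closed-form statistics are
checked against brute-force oracles at 1e-12. These sizes keep the whole
suite under a few minutes on one CPU while leaving each stochastic check
enough replicates for stable pass/fail behavior.

## A worked example

```{r example}
prof <- hr_profile_recovery(start = 155, asymptote = 75, tau = 50)
sim <- simulate_ppg(duration = 60, hr_profile = prof, noise_sd = 0.2,
                    seed = 5)
st <- run_step_test(sim$series, test_end = 0, age = 34, sex = 0)
st
```

```{r distance}
run <- simulate_track("line", speed = 3.3, duration = 720, jitter_sd = 3,
                      seed = 11)
d <- track_distance(run$track)
d
vo2max_run(d[["savgol"]])
```

## Known limitations

- The estimator assumes one quasi-stationary period per 10 s window;
  rapid HR changes within a window bias the estimate toward the window
  mean (acceptable for recovery curves with τ ≳ 30 s).
- Confidence is a periodicity score, not a motion-artifact detector; a
  strongly periodic artifact would pass QC.
- The equirectangular projection degrades beyond a few kilometers from
  the anchor and near the poles.
- Savitzky–Golay smoothing shortens high-curvature paths slightly
  (circle tests bound this at 1.5%); under heavy jitter the smoothed
  distance still overestimates, only less than the raw sum.
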