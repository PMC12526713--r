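---
title: "Classifying mechanical-ventilation weaning outcome from diaphragmatic sEMG and ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mechanical-ventilation weaning outcome from diaphragmatic sEMG and ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the signals

When a mechanically ventilated patient undergoes a spontaneous breathing
trial, the clinical question is whether extubation will hold: weaning
*success* means sustained spontaneous breathing (conventionally at least
48 h after extubation), *failure* means reintubation. `weanEMG` implements
an analysis chain that classifies that outcome from two non-invasive
recordings made during the trial: a 3-lead ECG sampled at 128 Hz and a
5-channel surface EMG of the diaphragm sampled at 1 kHz.

The chain condenses roughly an hour of raw signal into four *derived*
series that carry the cardiorespiratory physiology:

* **EDR** (ECG-derived respiration): the beat-to-beat peak-to-peak QRS
  amplitude, which is modulated by chest impedance changes over the
  respiratory cycle, interpolated with a shape-preserving (monotone
  Hermite) cubic so it never overshoots the measured amplitudes.
* **HRV**: the instantaneous heart rate `1/RR`, with a recursive outlier
  rule — while any point deviates from the series mean by more than 18% of
  that mean, the worst offender is replaced by spline interpolation from
  the currently acceptable points — then cubic-spline interpolation to a
  1 Hz grid and up to the common analysis rate.
* **EMGe**: the diaphragmatic activity envelope (rectified-peak spline with
  quadratic local smoothing).
* **EMGi**: the series interpolated through rectified peaks above an
  amplitude threshold (default the 70th percentile) with a minimum
  separation of 0.15 s, the larger peak winning a conflict.

All four live on a common uniform grid at the analysis rate `fa = 4` Hz.
One representative sEMG channel / ECG lead pair feeds the feature stages;
it is chosen by maximising the lagged cross-correlation between each EMG
envelope and each lead's EDR (lags up to ±5 s, signed maximum: coupled
respiratory drive raises both signals together).

## From signals to 320 features

A sliding outer window (300 s, 50% overlap — a 3600-s recording yields
exactly 23 windows) turns scalar descriptors into *time-varying* parameter
series:

* **Spectral band parameters.** Per window and signal, the Hann-tapered
  modified periodogram is summarised over the LF (0.04–0.15 Hz) and HF
  (0.15–0.4 Hz) bands by five descriptors: peak power `Hp`, peak frequency
  `Fp` (ties toward the lower frequency), trapezoidal band power `P`, and
  the up/down slopes `Us`/`Ds` from the band edges to the peak (zero and
  flagged when the peak sits on an edge). 5 descriptors × 2 bands × 4
  signals = 40 base parameters.
* **Coherence parameters.** Magnitude-squared coherence
  `K(f) = |Sxy|² / (Sxx·Syy)` is estimated within each outer window from
  60-s Welch sub-segments (50% overlap, 9 averages; at least 4 are required
  — a single segment gives `K ≡ 1`). For the four canonical pairs
  (EMGe–EDR, EMGe–HRV, EMGi–EDR, EMGi–HRV) the same five band descriptors
  plus the in-band RMS of `K` are computed over the combined modulation
  band 0.04–0.4 Hz, and `K` is read at two fixed frequencies (0.02 and
  0.04 Hz, nearest grid bin). 6 × 4 + 2 × 4 = 32 base parameters. The
  single-band convention is the only one consistent with the 80-parameter
  catalogue arithmetic; per-band extras remain available through the
  configuration.
* **Entropies.** Sample and approximate entropy of each signal per window,
  with embedding length `m = 2` and tolerance `r = 0.15 ×` the *window's*
  SD, Chebyshev distance. ApEn counts self-matches (always finite); SampEn
  excludes them and is `NA` when no template pair matches. 2 × 4 = 8 base
  parameters.

Each of the 80 base parameter series is summarised by four statistics —
mean, coefficient of variation `s/x̄`, kurtosis `Σ(x−x̄)⁴/(n·s⁴)` (sample
SD), and the interquartile range with type-7 quantiles — giving the
canonical 320-column feature matrix.

Feature selection is two-stage: a per-feature two-sided Mann–Whitney test
between outcome groups at raw `α = 0.05` (no multiple-testing correction,
deliberately), then greedy elimination on the Spearman correlation matrix
of the significant set until all pairwise `|ρ| < 0.6` (the member of a
violating pair with the larger mean `|ρ|` to all others is dropped; ties
resolve toward the larger p-value).

## Classification

Three classifiers operate on the retained features over repeated
stratified 70/30 train/test splits (default 1000): Gaussian Naive Bayes on
raw features (zero within-class variances floored at `1e-9 ×` the pooled
feature variance), k-nearest neighbours on z-scored features (any of ten
distance metrics, Spearman by default, majority vote with ties resolved
toward the smaller distance sum), and a polynomial-kernel SVM of degree 5
(via `e1071::svm`, `C = 1`). Weaning success is the positive class
throughout, pinning the sensitivity/specificity semantics. Sequential
backward elimination scores each candidate removal with a common seeded
set of splits (100 per step by default) and removes the feature whose
removal costs least, returning the full trace and the best set along it.

```{r example}
library(weanEMG)
spec <- cohort_spec(n_success = 19, n_failure = 21, duration = 600, seed = 1)
run <- run_weaning_pipeline(spec, wean_config(n_runs = 1000), seed = 1)
print(run)
```

## What the synthetic cohort emulates

The study data behind this kind of analysis are typically not
redistributable, so the package ships a generator whose *defaults are the
study conditions*: 19 successful and 21 failing patients, one-hour
recordings (tests and the acceptance script scale the duration down, see
below), 75 bpm mean heart rate with low-frequency (0.095 Hz) and
respiratory-phase RR modulation, 18 breaths/min (0.3 Hz, inside the HF
band) with breath-by-breath period jitter, QRS-like Ricker wavelets whose
peak-to-peak amplitude rides the shared respiratory phase, and broadband
(20–450 Hz) diaphragmatic activity amplitude-modulated by respiratory
bursts locked to that same phase. Channel 3 carries the strongest
respiratory locking and lead II the deepest EDR modulation, so the
cross-correlation step selects the (channel 3, lead II) pair by design.

The group contrasts mirror the qualitative physiology the analysis is
meant to detect:

* success: deeper EDR modulation (0.35 vs 0.10), deeper and more irregular
  envelope oscillation on a lower activity level, stronger phase locking
  (coupling 0.95 vs 0.75), larger breath-period variability (14% vs 2%)
  and RR jitter — hence higher spectral band powers, higher coherence and
  higher entropy;
* failure: higher overall diaphragmatic amplitude (tonic-dominated
  envelope, level ≈ 2× success) with shallow, regular modulation — hence
  higher EMG amplitude but lower modulation power and lower complexity.

Two design points deserve explanation because they were forced by the
physics of the measurement chain rather than chosen freely. First, the
additive sEMG noise floor is *absolute* (calibrated so the success-level
activity meets the target SNR, 15 dB by default) rather than proportional
to each recording's power: with proportional noise the shallow-modulated
failure group becomes noise-dominated after envelope extraction and its
measured entropy is spuriously *high*, inverting the intended contrast.
Second, the carrier concentrates most of its power below the 64 Hz
post-resampling Nyquist with a local-RMS-stabilised low band, because the
envelope of what survives resampling — not the envelope that was imposed —
is what the analysis measures.

The generator does *not* emulate: realistic ECG morphology (P/T waves),
motion or electrode artifacts, ECG contamination of the sEMG channels
(and the pipeline does not remove any), non-stationary clinical events, or
inter-patient diversity beyond seed-to-seed variation of one parameter
set. Green tests therefore demonstrate that the chain recovers designed
contrasts of this statistical structure — not clinical performance on real
recordings.

## Numerical choices

* Zero-phase filtering is forward–backward IIR with reflection padding
  sized to three time constants of the slowest pole; the 0.05 Hz ECG
  high-pass needs about a minute of padding for its transient to die out.
  Filters are Butterworth (order 4 high-passes; order-2 band-stop notch of
  quality factor 35). Filtering is idempotent to within ~1% RMS; at the
  128 Hz rate the 60 Hz notch sits at 94% of Nyquist and its skirt makes
  the second pass trim up to ~2% there.
* Resampling (1 kHz → 128 Hz) is an order-8 zero-phase anti-alias low-pass
  at 80% of the target Nyquist followed by linear interpolation onto the
  target grid; a 70 Hz tone survives at under 5% amplitude.
* Envelope series are band-limited at 0.8 Hz (twice the HF edge) before
  decimation to 4 Hz — spline-through-peaks ripple otherwise aliases into
  the analysis band. EMGe peaks are block maxima over ±40 ms neighbourhoods
  (single-sample maxima of a stochastic carrier are too volatile).
* The spike rule (robust z > 8 on the MAD scale, linear interpolation) is
  applied to the sEMG channels only: on ECG the QRS complexes themselves
  sit tens of MADs above baseline and any robust amplitude rule would
  excise them.
* SNR uses a Savitzky–Golay least-squares baseline in two variants: the
  smooth fit itself as signal estimate (slow signals; order 3, 0.5 s
  window) and a power-profile variant for raw burst-like channels, where
  the noise is the quiet floor (25th percentile) of the smoothed
  instantaneous power, with an order-1 fit because higher orders ring
  negative around bursts. Residuals at rounding level report `Inf`.
* The HRV outlier rule interpolates replacements from the *currently
  acceptable* points (clustered outliers otherwise feed each other) with a
  linear fallback if the spline overshoots; a hard iteration cap of 10×n
  raises an error.
* `Fp` ties break toward the lowest frequency; band edges belong to the
  band; fixed-frequency coherence values use nearest-bin lookup, not
  interpolation.
* All randomness fans out from one integer seed through a deterministic
  per-patient/per-stage hash, so any subset of a cohort is reproducible in
  isolation.

## Problem sizes used by the test-suite

The packaged tests run the full chain on 600-s recordings (three outer
windows) for single-patient checks and on twenty 30-patient cohorts of
480-s recordings (two outer windows) for the selection-recovery check;
classifier evaluations in tests use 200 repeated splits. These sizes are
the package's own choices for routine verification; the generator's
defaults remain the full one-hour study conditions.

## Known limitations

* The entropy statistics use a tolerance proportional to the per-window SD,
  which makes them scale-free but means slow deterministic structure
  (deep regular modulation) *lowers* measured entropy; contrasts must be
  interpreted relative to the modulation regime.
* The feature catalogue is computed for one selected channel/lead pair;
  per-channel catalogues are out of scope.
* No principal-component stage is implemented: the selection chain is
  significance + correlation filtering only.
* The EDF writer targets plain EDF with 1-s records and requires
  whole-second durations; 16-bit quantisation bounds round-trip accuracy
  at (channel range)/2¹⁵.
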