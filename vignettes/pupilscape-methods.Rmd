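---
title: "pupilscape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pupilscape: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the synthetic-data
generator emulates (and what it does not), and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The free-viewing model

The analysis treats pupil size as a slow, lagged, inverse readout of the
luminance falling near the point of regard. Its assumptions, in order of
importance:

* **Linearity over long timescales.** Pearson correlation between pupil
  size and per-cell channel intensity captures linear covariation over
  minutes of viewing. It deliberately ignores the ballistic shape of
  individual light responses; no impulse-response deconvolution is
  attempted (that is a documented non-goal).
* **A single fixed lag.** Pupil reactions trail their cause by roughly
  half a second. The pipeline estimates a per-subject, per-channel lag by
  cross-correlation (`estimate_lag`, peak = most negative r, since light
  and pupil size are inversely related) but the default analysis path uses
  a fixed 500 ms shift, i.e. 6 frames at the 12 Hz analysis rate.
* **Retinotopic-like coordinates.** Scene statistics are expressed in a
  700 x 700 px window centered on gaze (about +-7.6 degrees), downsampled
  by 10 into 70 x 70 cells, with off-screen cells NaN. Row < 35 (0-based)
  means above fixation.

Display nonlinearity is inverted per channel with
`L_c = scale_c (v/255)^gamma_c`; the fitted exponents of the reference
display are red 2.24, green 2.23, blue 2.22. Unit peak scales are the
default because Pearson correlation is invariant to positive affine
scaling; measured cd/m^2 peaks may be supplied when channel values
themselves are of interest. The CIELAB route assumes sRGB primaries and a
D65 white point (the display profile beyond gamma is unknown) and keeps
the CIE polarity convention (positive a* = red, negative b* = blue); maps
described with the opposite a* polarity can be matched by negating a*.

### Group inference

Correlations are variance-stabilized with Fisher's `z = atanh(r)`
(|r| clipped to 1 - 1e-7), then tested per cell with a one-sample t across
subjects, with Benjamini-Hochberg FDR control at q = 0.01 applied per map
over finite cells. Channel pairs are compared with the Hotelling-Williams
t for dependent overlapping correlations (df = n - 3), which requires the
channel-channel correlation r23 per cell; Steiger's Z is available behind
an argument because the literature uses both and the reference analysis
does not say which it used. The per-subject statistic maps are aggregated
by a second-level one-sample t, matching the group "t-score" maps the
design calls for; a pooled single-level mode was considered and rejected
as the default because it conflates within- and between-subject variance.

Low-coverage cells are excluded rather than imputed: a cell needs
`n_min = max(100, 5% of T)` paired samples (the source analysis is silent;
this guards edge cells whose coverage is dominated by off-screen NaN).
Zero-variance cells are NaN. The above-vs-below-fixation test is a Welch
two-sample t between the cells strictly above and strictly below the
central row (the row containing fixation is excluded); it ignores spatial
autocorrelation between cells, exactly as the field's version of this test
does — p-values for that test should be read accordingly.

## 2. Pupil preprocessing

* **Eye selection**: the eye with the smaller invalid fraction; ties go
  left. Averaging eyes is rejected because one-sided dropouts create
  artificial steps.
* **Velocity outliers**: velocities are first differences times the
  sampling rate; an offending velocity flags its *later* sample (the
  convention when the attribution is ambiguous). Exactly two passes, at
  2.0 then 2.5 SD of the velocity distribution (recomputed on survivors),
  then linear interpolation. The two-pass scheme is prescribed; no further
  iteration.
* **Blinks**: maximal runs of 50-500 ms of contiguous missing data.
  Longer runs are dropouts and stay missing. Repair smooths with a Hanning
  window (nearest odd sample count to 11 ms), extends each edge up to
  50 ms to the nearest sample whose smoothed |velocity| falls below a
  threshold, and interpolates linearly. The edge threshold is not stated
  numerically by the reference procedure; the default here is 3 x the MAD
  of the smoothed velocity, a robust data-driven stand-in, and it is
  configurable. Blinks whose padded spans overlap are repaired as one
  interval — interpolating each separately would anchor on the
  closure-contaminated sliver between them (this case is exercised by the
  acceptance suite).
* **Downsampling**: bin means over `[k/fs_t, (k+1)/fs_t)`, not decimation;
  means act as a crude anti-aliasing filter and define NaN bins cleanly.

## 3. The flashed-stimulus (PLR) pipeline

Percent signal change uses the 500 ms pre-stimulus baseline; a trial needs
at least half its baseline samples and a positive baseline mean. PLRmin is
the minimum of the *condition-mean* waveform on [0, 2] s inclusive
(epochs are averaged within condition before group statistics; a
per-trial-minimum mode exists behind an argument, and the minimum of a
mean is >= the mean of minima, so the modes are not interchangeable).
Trials with any missing sample in (0, 1500] ms are excluded whether or not
the gap is blink-shaped: the distortion concern is identical.

The 3 x 4 repeated-measures ANOVA is computed from orthonormalized
within-subject contrasts. Sphericity is assessed per effect with Mauchly's
test; the headline p-value is Greenhouse-Geisser corrected *only when
Mauchly rejects at .05*, because the procedure being implemented corrects
"violations" rather than correcting unconditionally — and an
unconditional GG default is measurably conservative for the 6-df
interaction at n = 15, which would distort the type-I calibration the
acceptance suite runs. Raw and GG-corrected p-values, the GG epsilon, and
both partial and generalized eta squared are always reported (an
unqualified eta-squared of a within-subject effect is ambiguous between
the two; both are given so either reading can be checked).

The six planned difference scores (top-bottom and left-right per color)
are tested with two-sided one-sample t-tests and BH-adjusted across
exactly those six p-values.

## 4. The synthetic world

The generator exists so that every stage has a parameter-recovery test
without any raw data. Its defaults *are* the stated world; they were
chosen once and are not tuned against test outcomes.

* **Scene**: a piecewise-constant layout — blue-dominant sky (mean RGB
  110/150/210) above a horizon, red/green-dominant terrain (150/120/70)
  below — whose region colors fluctuate as AR(1) processes
  (phi = 0.95 at 12 Hz, stationary SD 8 intensity levels, a ~1.7 s
  correlation time slow enough for the sluggish pupil to track). This
  captures what the correlation maps are sensitive to (region-specific
  channel dominance with slow temporal fluctuation); it does not emulate
  texture, perspective, shadows, or object motion, so a green test
  establishes statistical recovery, not photometric realism.
* **Gaze**: an OU-style walk. Vertical gaze rides the horizon line with
  ~0.2 deg jitter (SD 10 px at 1080-px full scale); horizontal gaze scans
  with SD 200 px. The tight vertical anchoring is the deliberate
  geometry of this world: it keeps the generative drive (below) loading on
  the sky series alone, so the "significant cells sit above fixation"
  recovery criterion is well-posed. With gaze biased below the horizon,
  terrain rows enter the upper window half and the terrain series leaks
  into the drive, which smears weak but *consistent* correlations over
  the whole lower half — a real property of gaze-contingent analyses
  worth knowing about, demonstrated by changing `center_offset_px`.
* **Pupil**: `pupil = baseline - gain * (drive ⊛ h)(t - lag) + noise`,
  drive = kernel-weighted mean of the gamma-transformed gaze window
  (default kernel: uniform over upper-half blue cells), baseline 1000 a.u.,
  gain 2000 a.u. per unit drive, Gaussian noise SD 10 a.u. at 300 Hz,
  blinks at 15/min (50-450 ms, flanked by 20 ms partial-closure ramps so
  the repair padding is genuinely exercised), spikes at 2/min. The scene
  is held piecewise-constant between frames (zero-order hold), which is
  what a display does and makes the noiseless single-cell case exactly
  r = -1 at the generative lag.
* **Impulse response**: the gamma family `h(t) = t^n exp(-n t / t_max)`
  with the conventional n = 10.1, t_max = 930 ms — simulator defaults,
  not claims about any particular dataset. Note the lag semantics: the
  cross-correlation peak recovers `lag` only under a delta IRF; under the
  gamma IRF the peak sits at lag plus the IRF's own group delay (~1 s).
  The lag-recovery acceptance run therefore uses the delta IRF, and a unit
  test documents the displacement under the gamma IRF.
* **Flashed stimuli**: epochs `B (1 + A/100 * h_norm(t)) + noise` with
  `h_norm` peaking at exactly 1 (so noiseless PLRmin equals A), condition
  amplitudes red -37.7, green -37.2, blue -44.3 percent with an extra
  -4 for blue-top, between-subject SD 3, per-trial SD 3, sample noise
  5 a.u. on a ~920 a.u. baseline, blink probability 0.15, n = 15
  subjects, 5 repetitions.

## 5. Numerical choices

* Pairwise-complete correlation maps are computed with masked
  cross-products (pupil pre-centered; channel values are O(1)); the test
  suite holds this to 1e-12 against a naive per-cell loop.
* `fisher_z` clips |r| at 1 - 1e-7; `atanh(1)` would be infinite.
* Gamma fitting profiles the scale out analytically and optimizes the
  exponent on (0.2, 8); it requires >= 4 distinct levels including a high
  one (max >= 192) because the exponent is ill-determined from dark
  levels alone.
* Gaze coordinates are 0-based, origin top-left, y downward, rounded to
  the nearest pixel before windowing; an off-screen or missing gaze
  yields an all-NaN window rather than dropping the frame, preserving
  time alignment.
* Williams t returns exactly 0 when r12 = r13 and rejects correlation
  triples whose 3 x 3 determinant is negative beyond 1e-8.
* The BH step-up is implemented directly (sorted threshold comparison)
  and is checked against both a brute-force O(m^2) oracle and
  `stats::p.adjust`.
* Reduced-resolution testing: recovery runs generate scenes at 1 px per
  map cell (80 x 80 screens, window half 35, block factor 1) instead of
  10 px per cell. Every pipeline stage is identical; for piecewise-
  constant scenes the 10 x 10 block mean is exact, so nothing is lost but
  compute. Geometry-dependent gaze parameters scale by the same factor
  of 10.

## 6. Known limitations

* Only non-negative lags are searched (pupil never leads the scene); the
  granularity is one frame.
* MP4 decoding is unavailable in this build's dependency set; frames are
  read from PNG directories.
* No pupil foreshortening correction, no binocular averaging, no
  convolutional deconvolution of the pupil series, no spatial
  cluster-based inference — all deliberate non-goals.
* The ANOVA requires a complete balanced table; subjects with missing
  cells are dropped with a warning rather than imputed.
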