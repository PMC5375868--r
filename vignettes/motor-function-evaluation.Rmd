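---
title: "Evaluating upper-limb motor function from fused IMU and surface EMG recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating upper-limb motor function from fused IMU and surface EMG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After a stroke, upper-limb motor function is routinely graded with the
upper-extremity component of the Fugl-Meyer assessment (FMUE): 33 items,
each scored 0–2 by a clinician, for a total of 66 points. The scale is
subjective, coarse, and requires a trained rater. `motorei` implements a
sensor-based alternative: the subject wears two six-axis inertial
measurement units (IMU1 on the forearm, IMU2 on the upper arm, 100 Hz) and
ten surface EMG channels (an eight-electrode forearm ring plus biceps and
triceps, 1000 Hz), performs eleven canonical upper-limb tasks three times
each, and the recordings are reduced to a one-dimensional *evaluation
indicator* (EI) per task and a global EI on the familiar 0–66 scale.

The package covers the entire chain: session I/O, filtering, repetition
segmentation, feature extraction, similarity scoring against a healthy
reference bank, four factorization-based indicator models, the
leave-one-subject-out (LOSO) validation protocol, and a synthetic-cohort
generator that stands in for clinical recordings, which are not publicly
available.

## Pipeline and model

### Preprocessing

EMG channels are band-pass filtered with a 2nd-order Butterworth design,
nominally 20–500 Hz. At a 1000 Hz sampling rate the 500 Hz upper edge sits
exactly on Nyquist and is unrealizable, so the filter is designed for
20–495 Hz; at envelope scale the difference is negligible, and a pure 20 Hz
high-pass is available through the `band` argument. IMU axes are low-pass
filtered at 20 Hz (2nd-order Butterworth). Both filters are applied
zero-phase (forward–backward, with odd-reflection padding of three periods
of the lowest design frequency) so that EMG and IMU streams stay aligned at
segment boundaries; whether the original analysis filtered causally or
zero-phase is not documented, and the choice is recorded in
`pipeline_config()`.

### Segmentation

The activity series is the summed instantaneous vector magnitude of the two
gyroscopes, \(S(t) = \lVert g_1(t)\rVert_2 + \lVert g_2(t)\rVert_2\)
(deg/s). A repetition starts at the first sample with \(S(t)\) strictly
above the threshold \(T_R = 3\) deg/s and ends at the last above-threshold
sample followed by at least 2 s below threshold; shorter dips are bridged,
so a momentary pause does not split a repetition. Gyroscope-based (rather
than EMG-based) segmentation matters for stroke subjects, whose incomplete
relaxation leaves EMG activity after movement ends. Two package-level
decisions the protocol leaves open: segments shorter than 0.3 s are
discarded as twitches, and a recording that ends before a full 2 s hold
closes the last segment at the final sample with an `open_ended` flag. All
boundaries detected on the 100 Hz clock are carried to the 1000 Hz EMG
clock by the exact 10:1 ratio.

### Features

Each segment yields:

* **Motion data profile (MDP)** — a 22 × 256 matrix: 10 EMG envelopes
  (256 ms rectified-mean window, 8 ms step), jointly normalized by the
  maximum across the ten channels; 6 accelerometer and 6 gyroscope axes,
  each group jointly normalized by its maximal absolute value; every row
  resampled to 256 points by linear interpolation. Amplitude normalization
  is applied after time resampling so the extreme value 1 is attained
  exactly. Row order is fixed as EMG 1–10, ACC1.xyz, ACC2.xyz, GYRO1.xyz,
  GYRO2.xyz (the convention is the package's; only the 10+6+6 split is
  prescribed). Envelopes are resampled rather than resampling raw EMG
  before enveloping, because the envelope is the coarser, numerically
  gentler series.
* **Supplementary features** — duration; the summed count of strict local
  extrema over the 12 filtered IMU axes (plateaus count once; counting on
  filtered, pre-normalization axes suppresses quantization extrema);
  EMG and per-device IMU power distributions (RMS fractions); forearm /
  upper-arm intensity ratios; and mean/max of each device's magnitude
  series. RMS-type features use the filtered, *unnormalized* signals, so
  they retain intensity information that the MDP's normalization removes.

### Reference bank and preliminary indicators

All healthy repetitions of a task form the reference bank (48 entries for
16 healthy subjects). A test repetition receives seven similarity
indicators: maximal Pearson correlation between flattened MDPs, minimal DTW
distance between MDPs (22-channel frames, Euclidean local cost, steps
(1,0)/(0,1)/(1,1), no window, no path normalization), and minimal Euclidean
distances for the EMG and four IMU power distributions. Per task the
indicators are averaged over the three repetitions; summing one component
over the 11 tasks gives the global preliminary EI. When the test subject is
healthy their own repetitions are removed from the bank — the tests enforce
this with a leakage canary (an unpurged bank returns PCC exactly 1).

Flattened-matrix correlation is the minimal reading of "correlation between
MDPs"; DTW is retained on the time-normalized profiles because the protocol
applies it there, even though length normalization already equalizes
durations. The bank aggregation for the power distances mirrors the DTW
treatment (minimum, then repetition mean).

### Factorization models

Per task, rows of the feature matrix \(V_{m\times 19}\) (7 indicators + 12
supplementary features, fixed column order) are mapped to a single raw
score, \(V \approx W_{m\times 1} H_{1\times 19}\):

* **PCA** — leading eigenvector of the covariance of the centered matrix.
* **MDS (Sammon)** — 1-D embedding minimizing
  \(\mathrm{Stress} = \frac{1}{\sum_{i<j} d^*_{ij}} \sum_{i<j}
  (d^*_{ij}-d_{ij})^2 / d^*_{ij}\), run from the PCA projection and from a
  seeded jittered start, keeping the lower-stress solution (never worse
  than the PCA start). Because an embedding alone has no out-of-sample
  rule, an OLS linear map from features to the embedding is fitted and used
  as the transform; duplicate rows are perturbed by a seeded 1e-9 jitter so
  no \(d^*_{ij}\) vanishes.
* **NMF** — rank-1 multiplicative Frobenius updates with seeded random
  initialization; the \(W\) column is renormalized each sweep with a
  compensating rescale of \(H\), so the product and the reconstruction
  error are unchanged and the error is provably non-increasing. Features
  enter min-max scaled to [0, 1] (test rows clipped), since NMF requires
  nonnegativity. Out-of-sample rows are scored by the nonnegative
  projection \(\max(0, vH^\top / HH^\top)\), used uniformly for training
  and test rows so identical rows always score identically.
* **LASSO** — coordinate descent on \(\lVert Vz - y\rVert_2^2 +
  \lambda\lVert z\rVert_1\) with the FMUE-related item scores as \(y\) and
  an unpenalized intercept; \(\lambda\) is chosen by seeded 5-fold
  cross-validation over a 20-point logarithmic grid with warm starts down
  the path.

For PCA/MDS/LASSO the features are z-scored with training-fold statistics
(the protocol states only that \(V\) is "centralized" for PCA; scaling
makes the heterogeneous units commensurable).

Two points the protocol leaves genuinely open, decided here once:

* **Orientation.** A 1-D component has an arbitrary sign. The component is
  oriented so that it correlates positively with the `pcc` feature, a known
  higher-is-better column. For PCA/MDS/LASSO this is a sign flip; NMF
  scores cannot be negated, so a negatively oriented NMF component is
  reflected about the training midrange (`raw' = max + min − raw`), which
  preserves nonnegativity.
* **Full-score normalization.** "Normalized to the full score" could anchor
  on the healthy mean, healthy max, or global max. The package anchors on
  the healthy training mean — component EI = `full_score · raw /
  mean(raw over healthy training rows)`, clipped to `[0, full_score]` —
  which is the same convention the protocol itself uses globally (healthy
  mean expanded to 66).

### LOSO protocol and validation metrics

With \(n\) subjects, \(n\) folds are run; in each fold the held-out
subject's data appear nowhere — not in the reference bank, the
standardization constants, or the model fit — and the preliminary
indicators of training rows are themselves computed under the bank
exclusions of that fold (implemented as exact max/min reductions over a
precomputed pairwise similarity cache, which is mathematically identical to
recomputing each fold from scratch). The global EI is the sum of the 11
component EIs; one expansion factor (66 / healthy mean) is applied to all
subjects, making the healthy mean exactly 66 by construction — this
protocol identity is what the acceptance script recomputes. Reported
metrics: the normal range (healthy mean ± 1.96 SD; sample SD, n−1, with a
population-SD option), the normal data variation rate
(NDVR = 100 · 1.96 · SD / mean, lower is better) and the determination
coefficient (DC, the R² of regressing FMUE totals on global EIs).

## The synthetic cohort

No public recordings exist for this protocol, so `generate_cohort()`
emulates the study conditions: 16 healthy and 18 impaired subjects, 11
tasks, one trial of three repetitions per task, with repetitions separated
by ≥ 2.5 s of rest. Movement is a smooth squared-sine angular-velocity
pulse on task-specific gyroscope axis weights (peak ≈ 120 deg/s · 1.8
summed magnitude), accelerometer profiles follow the pulse derivative under
constant gravity components, and EMG is an envelope-modulated band-limited
(20–450 Hz) Gaussian carrier — matching the envelope-level features the
pipeline uses without simulating motor-unit physiology. Impairment level
\(\ell \in [0,1]\) acts through four mechanisms: slowing (duration ×
\(1+0.6\ell\)), weakness (amplitude × \(1-0.5\ell\)), 5 Hz gyroscope tremor
(8 deg/s at \(\ell = 1\); 5 Hz lies inside the 20 Hz IMU passband so it
survives preprocessing and inflates extremum counts), and co-contraction
(a fraction \(0.6\ell\) of the biceps envelope mixed into the triceps
channel). Healthy subjects carry small level jitter (|N(0, 0.015)|) plus
±10% per-subject time-warp and amplitude jitter, so the normal range is
nontrivial and leakage is detectable; impaired levels are spread evenly
over [0.05, 0.8]. FMUE-like item scores are
`round(full_score·(1−ℓ) + noise)` clipped to range, with a rescaled
residual placing the total on the 0–66 scale; healthy subjects are fixed at
66 with full item scores. Every trial stores the threshold crossings of its
noiseless activity series as ground truth, which the segmentation tests
recover within ±1 IMU sample.

What the generator does **not** emulate: real motor-unit statistics,
electrode placement variability, sensor drift, gravity reorientation during
movement, or clinically realistic FMUE rater noise. Passing tests therefore
demonstrate that the pipeline recovers the impairment structure it is
pointed at, not clinical validity on real recordings; the study's reported
NDVR/DC values were measured on 34 subjects' clinical data and are not
reproducible from synthetic cohorts.

## Numerical choices and degenerate inputs

* Envelope windows are fully contained in the segment; a segment shorter
  than one window falls back to a single whole-segment window, flagged.
* All-zero channel groups in the MDP are left as zeros rather than divided.
* Zero-variance flattened profiles are skipped in the PCC maximum (error if
  none remain); a zero denominator in an intensity ratio reports a
  configurable cap with a flag.
* NMF updates add 1e-12 to denominators; LASSO coordinate descent converges
  on the maximum coefficient change (1e-12 for final fits, 1e-6 within the
  CV path, which only ranks λ candidates).
* Sammon MDS runs at most 200 iterations at tolerance 1e-8 per fit; if the
  optimizer fails or ends above the PCA-start stress, the PCA start is
  retained, so the embedding is never worse than its linear initialization.
* If a degenerate small fit centres the healthy rows at or below zero raw
  score, the raw scale is shifted so the training minimum sits at zero
  before the full-score normalization (the anchor needs a positive healthy
  mean); on realistic cohort sizes the shift never triggers.
* Per-fold, per-task seeds are derived arithmetically from the master seed,
  keeping every stochastic fit (MDS start, NMF init, LASSO folds)
  reproducible; all derived seeds stay below 2^31.

## Problem sizes

The default cohort (34 subjects × 11 tasks × 3 repetitions = 1122 segments)
is the scale the package is exercised at: preparing it — including the
~54 000 cached DTW alignments of 22 × 256 profiles — takes a few minutes on
one core, and each LOSO evaluation takes seconds (PCC/DTW/PCA) to about a
minute (LASSO). The unit-test fixtures use a 2-task, 8-subject
configuration of the same generator, which runs the identical code paths in
a few seconds.

## Known limitations

* The MDS out-of-sample map is linear; if the Sammon embedding is strongly
  nonlinear in feature space the mapped test scores degrade, which shows up
  as a higher NDVR for the MDS route than for PCA/NMF on some cohorts.
* Component EIs are clipped at the task full score, so the indicator cannot
  express above-normal performance; this matches the clinical scale but
  compresses healthy-side variance.
* The per-task normalization anchors on the healthy mean; with very few
  healthy training subjects the anchor is noisy.
* DTW on time-normalized profiles measures shape differences only; residual
  duration information enters solely through the duration feature.
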