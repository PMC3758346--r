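---
title: "Methods: event-related fTCD lateralization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-related fTCD lateralization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftcdlat)
```

## The measurement and the analysis chain

Functional transcranial Doppler sonography records the spectral-envelope
blood flow velocity of both middle cerebral arteries at 25 Hz while the
participant alternates between target intervals (task execution, 25–35 s,
mean 30 s) and control intervals (matched baseline activity, 15–25 s, mean
20 s), twenty target/control pairs per block. The signal at this stage is
dominated by cardiac pulsatility (tens of percent of the mean velocity),
while the task-related hemodynamic response is a few percent — so the
pipeline's job is separation of time scales followed by event-locked
averaging:

1. **Cardiac cycle integration.** Systolic peaks are detected on the left
   channel (both arteries share the same heart, so one set of cycle
   boundaries applies to both — this guarantees identical integration
   windows for the left–right subtraction later). Cycle boundaries are the
   diastolic minima between successive peaks; cycles outside physiological
   duration bounds (30–200 bpm) are discarded. Each channel is replaced by
   its per-cycle means, linearly interpolated at cycle midpoints and
   resampled on the original 25 Hz grid, constant beyond the first/last
   midpoint. The interpolation scheme is a choice (the integration step is
   conventionally described but not specified at the resampling level);
   per-cycle mean + midpoint interpolation reproduces a linear velocity
   trend exactly up to one cycle of lag, which the tests assert.
2. **Epoch segmentation and normalization.** A window of [−5, +25] s around
   every target onset. The baseline `V_b` is the mean over [−5, 0) — the
   final 5 s of the preceding control — per channel and epoch; the trace
   becomes `dv(t) = 100 (V(t) − V_b)/V_b`. The window extends to +25 s so
   that the 2–18 s activation window and 5 s moving windows starting at
   +15 s fit with margin. Epochs lacking a complete window are dropped with
   a warning; a non-positive baseline marks the epoch bad rather than
   producing undefined percentages.
3. **Artifact screening.** An epoch is bad when |dv| > 30 anywhere in the
   window on either channel. The inequality is strict (exactly 30% is
   kept), the baseline span is included in the screened range, and the rule
   is applied to baseline-normalized data — three details the conventional
   description leaves open; the package fixes them this way and tests the
   boundary. Screening is idempotent.
4. **Subject QC.** A subject is excluded when any condition retains less
   than 80% good epochs; 16/20 = 0.80 is retained, 15/20 is not.
5. **Average, then filter.** Good epochs are averaged pointwise per channel
   and the average is filtered with a second-order zero-phase Butterworth
   low-pass at 1 Hz (filtering the average, not the single trials, follows
   the conventional order). The forward–backward pass squares the magnitude
   response, so the gain at the cutoff is 0.5; DC gain is exactly 1.

The lateralization trace is `ΔV(t) = dv_left(t) − dv_right(t)`, computed
pointwise with no further processing.

## The lateralization index

`LI` is the time-average of ΔV over a 2 s window centered at
`t_max = argmax |ΔV|` inside the activation window (default [2, 18] s after
onset). Positive LI = left dominance. Numerical choices:

* The average is the **trapezoidal time-average** (integral divided by
  window length), not the plain mean of grid samples. For a piecewise-linear
  trace with nodes on the grid the trapezoid is exact, which makes the
  worked example in the tests (a triangular ΔV peaking at 5% at 10 s gives
  LI = 4.6875% exactly) independent of the sample rate. A plain inclusive
  sample mean would differ by half a sample step at the window edges.
* Ties at the peak resolve to the earliest sample.
* If `t_max` falls within 1 s of the trace end, the integration window is
  clipped to the trace rather than shifted, preserving "centered at the
  peak" as nearly as possible.
* An activation window with no samples is an error, not an NA.

## Group statistics

* **Group traces**: pointwise mean ΔV across subjects with the SEM
  (sample SD / √n).
* **LI correlation**: Pearson r between the two tasks' per-subject LIs,
  two-sided p, and the least-squares line for scatter plots.
* **Moving-window correlation**: for each 5 s window starting between −5
  and +15 s (step = one sample, 0.04 s, producing a continuous curve; the
  conventional analyses do not state a step), each subject's mean ΔV over
  the half-open window is computed per task, and the correlation across
  subjects between tasks is reported with an uncorrected two-sided p. The
  threshold shown is `critical_r(n, 0.05)`, the |r| at which the t-transform
  p crosses 0.05 with n−2 degrees of freedom. No correction is applied
  across window offsets — the per-window thresholds are deliberately
  uncorrected and therefore anticonservative as a family.
* Windows with zero variance across subjects in either task yield `NA`
  (a broken curve), never an imputed 0.

## The synthetic cohort simulator

No public fTCD recordings accompany this analysis style, so the simulator
is a first-class module with known ground truth. It emulates:

* **Cardiac carrier**: an asymmetric pulse (raised-cosine systolic upstroke
  over the first quarter cycle, normalized exponential diastolic decay)
  with cycle mean exactly equal to the subject's baseline velocity and
  peak-to-trough modulation `pulsatility_fraction × baseline`. A pure
  sinusoid would make cycle detection degenerate; the asymmetric shape
  exercises it realistically. Heart rate drifts sinusoidally by ±5% within
  a session (period ~1 min, random phase); there is no arrhythmia model.
* **Hemodynamic response**: a gamma-form rise that is zero at onset, peaks
  at exactly the requested amplitude at `hrf_peak_delay_s` (default 6 s,
  consistent with task-evoked CBFV peaks at ~5–7 s), then decays with a
  Gaussian taper to a sustained plateau (`hrf_plateau_frac`, default 0.6)
  lasting through the target interval, tapering back to baseline after the
  target ends. The response multiplies the carrier, so percent
  normalization downstream recovers it directly. A brief bilateral
  post-onset dip is available (`initial_dip_pct`) but off by default — it
  is phenomenology seen in some motor tasks, not part of the method.
* **Lateralization trait**: per subject, a latent standard-normal draw
  shared across tasks with correlation `trait_cross_task_correlation`
  (via `u = sqrt(|ρ|)·z + sqrt(1−|ρ|)·e`), converted to per-hemisphere
  amplitudes `effect ± trait_sd · u / 2`. The injected cross-task
  correlation of true ΔV amplitudes equals ρ by construction, which the
  tests verify at n = 500 within ±0.05.
* **Noise and artifacts**: additive white noise (percent of baseline) and,
  per target epoch with probability `artifact_rate_per_epoch`, one square
  pulse of 0.5–2 s, random sign and channel, amplitude
  `artifact_amplitude_pct` (> 30 by validation so artifacts can trip the
  screen). Note that cardiac-cycle integration averages a sub-cycle pulse
  over its cycle: a 0.5 s, 50% pulse at a slow heart rate can fall below
  the 30% threshold after integration, exactly as brief real artifacts can.
  Test fixtures that need a deterministic rejection count therefore inject
  artifacts of 1.5 s at 55–60% via `inject_artifact()`.

Default condition choices (set once, with their rationale): effects
left/right of 5.0/2.5% (language) and 2.6/5.0% (knapping) so the mean
injected ΔV is ≈ +2.5% and −2.4% — the magnitudes typical of word-generation
and visuomotor fTCD studies; `trait_sd_pct = 2.5` (between-subject SDs of
2–4% are typical); `trait_cross_task_correlation = 0.74`; noise SD 4%;
artifact rate 0.1/epoch; heart rate 55–85 bpm; baseline velocity
45–65 cm/s; pulsatility 0.5.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: respiration and CO₂ reactivity (slow oscillations
that real baselines contain), probe-angle drift, cue-evoked auditory
transients, task-correlated motion beyond square pulses, and any
time-course structure in the cross-task coupling. The last point matters
for interpretation: because one scalar trait scales a subject's whole
response, the simulated moving-window correlation is roughly flat across
the response, whereas real paired-task data can show coupling confined to
early windows. The simulator validates the machinery, not the physiology.

## Numerical choices and degenerate inputs

* Filter edge handling: 5 s of odd (point-reflected) padding at each end
  before the forward–backward pass, trimmed afterwards. The 30 s epoch
  windows are short relative to a 1 Hz filter's transient; the padding
  absorbs it (transients decay by ~14 orders of magnitude across the pad).
  Time-reversal symmetry of the result holds to ~1e−13; tests assert 1e−9.
* Cycle detection needs ≥ 10 s of signal and ≥ 5 plausible cycles;
  constant input raises a "no cardiac signal" error.
* Averaging with zero good epochs is an error ("no usable epochs"), not an
  empty trace.
* All cohort randomness flows from `config$seed`; identical configs give
  bit-identical cohorts and byte-identical pipeline CSV outputs.
* CSV dialects write numerics with 9 decimal places so write-then-read
  round trips reproduce values to 1e−9.

## Problem sizes used by the test suite

Unit tests run on single sessions (1–20 epochs). The cohort-level
correlation-recovery and type-I-calibration properties use 100 replicate
cohorts of 10 subjects × 2 tasks × 20 epochs each for both ρ = 0.9 and
ρ = 0 (about 4,000 simulated sessions end to end); the critical-r check
draws 10⁶ null correlation samples. The acceptance script analyses one
default-conditions cohort (10 subjects).

## Known limitations

* Left-handed subjects are not modeled differently (no sign-flipping
  convention is applied; analyses that pool handedness groups should do so
  deliberately).
* The ±30% rule's exact historical scope (raw vs normalized, sub-window)
  is not documented in the conventional descriptions; the package's choice
  (normalized, full window, strict) is explicit and tested, not asserted
  as anyone else's intent.
* No bootstrap confidence intervals on individual LIs, and no group-level
  inference on LI means against zero — the group outputs are descriptive
  plus the two cross-task correlation analyses.
* No reader for proprietary instrument formats; the documented CSV export
  convention is the ingestion contract.
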