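# ftcdlat

Event-related lateralization analysis for functional transcranial Doppler
sonography (fTCD).

fTCD measures cerebral blood flow velocity (CBFV) simultaneously in the left
and right middle cerebral arteries with head-mounted Doppler probes while a
participant alternates between a target task (e.g. cued word generation, or
shaping a stone tool) and a matched control interval. Because the envelope
velocity is dominated by cardiac pulsatility, and single trials by
non-task-locked variability, hemispheric dominance is estimated by a standard
chain: integrate the envelope over cardiac cycles, segment into onset-locked
epochs, normalize each epoch to its 5 s pre-onset baseline, screen out
implausible trials, average, and low-pass filter. `ftcdlat` implements that
chain, the lateralization index computed from it, and the group statistics
that compare lateralization across two tasks — plus a synthetic cohort
simulator with known ground truth, so the whole pipeline is testable without
access to any recordings.

## The quantities computed

For each target epoch and hemisphere, velocity is expressed as percent change
relative to the pre-onset baseline `V_b` (mean over the 5 s of control
immediately preceding onset):

    dV(t) = 100 * (V(t) - V_b) / V_b            [%]

The lateralization trace is the left-minus-right difference of the averaged,
filtered percent-change responses:

    ΔV(t) = dV_left(t) - dV_right(t)            [%]

The lateralization index is the time-average of ΔV over a `t_int = 2 s`
window centered at the peak absolute lateralization within the activation
window (2–18 s after task onset by default):

    LI = (1 / t_int) ∫ ΔV(t) dt  over  [t_max - 1 s, t_max + 1 s]

with `t_max = argmax |ΔV(t)|`. Positive LI means left-hemisphere dominance.

Screening follows the conventional rules: an epoch is rejected when |dV|
exceeds 30% anywhere on either channel, and a subject is excluded when any
condition retains fewer than 80% good epochs. Averages are filtered with a
second-order zero-phase (forward–backward) Butterworth low-pass at 1 Hz.

At the group level the package computes mean ΔV traces with SEM bands, the
cross-task Pearson correlation of the per-subject LIs, and a moving-window
correlation: for every 5 s window starting between −5 and +15 s relative to
onset, the correlation across subjects between the two tasks' mean ΔV in
that window, with uncorrected two-sided significance thresholds.

## Worked example

```r
library(ftcdlat)

cfg    <- ftcd_config(n_subjects = 10, seed = 1)   # default study conditions
cohort <- simulate_cohort(cfg)

sess <- cohort$sessions[["S03_language"]]
sess
#> fTCD session S03 / language: 25416 samples at 25 Hz (1016.6 s), 20 targets

pp <- preprocess_session(sess)    # cycles -> integration -> epochs -> screen -> filter
pp$epochs
#> fTCD epochs S03 / language: 19/20 good, window [-5, 25] s

li <- lateralization_index(delta_v(pp$response))
li
#> LI S03 / language: +0.078% (left dominant), peak at 15.04 s, window [14.04, 16.04] s

subset(cohort$truth, subject_id == "S03")[, 1:4]
#>   subject_id task_label true_delta_v_pct latent_trait
#> 5        S03   language      -0.08901674   -0.8356286
#> 6        S03   knapping      -4.10203521   -0.8356286
```

The recovered LI (+0.078%) matches this subject's injected left-minus-right
amplitude (−0.089%) to within the simulator's noise: one epoch of twenty was
rejected by the ±30% screen, and a near-zero lateralization is correctly
reported as near zero. Strongly lateralized subjects (e.g. S03's knapping
session, injected ΔV = −4.1%) come back with correspondingly large negative
indices.

The full pipeline — simulate, preprocess, QC, LI, group correlation — runs
from one call and writes every artifact (CSV tables, `manifest.json`,
optional figures):

```r
run_pipeline(cfg, "out/")          # or: Rscript inst/cli/ftcdlat.R run --config cfg.yaml --out out
```

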