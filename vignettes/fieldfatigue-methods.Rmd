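---
title: "Methods: single-sensor fatigue prediction on synthetic field sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sensor fatigue prediction on synthetic field sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fieldfatigue)
```

## The problem

Fatigue degrades both motor output and decision-making, but standard
assessments (finger tapping, vertical jump, Stroop and similar) interrupt
the activity being studied.  The analysis implemented here asks whether a
single chest sensor — 100 Hz tri-axial acceleration plus 250 Hz single-lead
ECG — carries enough information to regress a continuous fatigue state
during self-paced trail exercise, once the confounders of terrain, slope
and activity type are handled by training activity-specific models.

No field recordings ship with this package.  Instead a synthetic-session
generator produces complete protocol runs with known ground truth, which
serves two purposes: every downstream stage has something realistic to
operate on, and — more importantly — the analysis becomes *falsifiable*:
we can ask whether the full pipeline recovers a fatigue trajectory that we
know, and whether it finds nothing when there is nothing to find.

## The synthetic protocol session

One session is `n_laps` repetitions of: a 3.8 km loop with 200 m of climb,
divided into 23 sections by changes of surface, slope or obstacle, followed
by a 10-minute seated test block.  Ground speeds are fixed per gait and
slope (run 2.0–3.0 m/s, walk 1.0–1.35 m/s), cadences default to 165
(run) and 112 (walk) steps/min, and a latent fatigue state `f(t)` rises
linearly from 0 to 0.6 over the session by default.

**Gait accelerometry.** Nothing in the source analysis describes its
signals generatively, so the generator commits to a simple controllable
model: each step is a sum of two Gaussian lobes in step phase (an impact
lobe and a smaller roll-off lobe), with per-surface templates — harder
surfaces get sharper, larger impact lobes.  The vertical channel oscillates
around +1 g.  Fatigue acts through two hooks: per-step peak amplitude is
scaled by `1 − 0.3 f` (reduced peak force) and per-step timing/amplitude
jitter grows with `f` (gait variability).  The template shapes guarantee
that the mean-removed vertical signal crosses zero upward exactly once per
step, which is what makes cadence-by-zero-crossings exact on clean input.
The fatigue-amplitude coefficient is a free parameter of the generator, not
an empirical claim — the source material describes the effect only
qualitatively.

**ECG.** A PQRST-like Gaussian-lobe beat train whose instantaneous rate
follows activity load (run 155, walk 120, sit 85 bpm) plus a `25 f` bpm
fatigue drift, smoothed over 60 s; beat-offset geometry compresses at short
RR so complexes never collide.  Additive 0.25 Hz sinusoidal baseline wander
(0.1 mV) and white noise ensure baseline correction is actually exercised.

**GPS.** 1 Hz positions interpolated along the loop (waypoints on a circle
whose circumference equals the lap distance) with 2.5 m horizontal and 3 m
vertical noise — the vertical noise is what makes slope classification a
statistical problem rather than a lookup.

**Performance tests.** Each test score is an affine function of `f(t)` plus
Gaussian noise, scored twice per lap (post-physical and post-cognitive).
Slopes and noise levels are set so the battery reproduces the expected
sensitivity pattern: vertical jump and dominant-hand finger tapping highly
correlated with protocol time, PVSAT and spatial memory essentially
uncorrelated.  The noise level for the tapping test was calibrated once
against a Monte-Carlo oracle (decline of 0.05 normalized units/hour over 12
hourly tests, noise sd 0.11, expected sensitivity R² 0.74) and frozen.

**What the generator does not emulate.** Biomechanically valid gait, ECG
pathology or HRV structure, GPS multipath/dropout, missing data, device
clock drift, or any coupling between cognitive load and movement.  Passing
tests therefore demonstrate that the *pipeline* is correct and that the
model can recover a signal of this kind at these noise levels — not that
the method achieves any particular accuracy on real recordings.

All randomness flows from the single session seed through one RNG stream
consumed in a fixed order (accelerometer segments, ECG, GPS, test scores),
so sessions are reproducible bit-for-bit.

## Activity labelling

Cadence is estimated per second from positive-going zero crossings of the
mean-removed vertical channel in a 5 s centred sliding window (the label
resolution is one second; the window length is this package's choice).
Before counting, the signal passes a 150 ms running-mean low-pass: white
sensor noise otherwise dithers extra crossings wherever the signal lingers
near zero, while gait fundamentals (1.8–2.8 Hz) are attenuated by under 5%.
With a 5 s window one crossing is 12 steps/min of resolution — coarse, but
far from the 100 and 150 steps/min decision thresholds.

The thresholds are read strictly as the inequality chain
`100 < walk < 150 ≤ run`: exactly 100 → `other`, exactly 150 → `run`.  The
convention is documented here so it can be flipped; it matters only for
cadences landing exactly on a threshold.

Waypoint crossing times are the track timestamps of minimal great-circle
distance to each waypoint, searched (for multi-lap sessions) within a
±20%-of-lap window around the waypoint's expected cumulative distance so
that repeated laps do not alias; the track is smoothed over 21 s first so
GPS noise neither inflates cumulative distance nor jitters the argmin.  A
waypoint never approached within 50 m is flagged, not silently assigned.
Slope per section uses the mean GPS altitude *at each waypoint*, pooling
all fixes within 10 m across laps (the seated block parks on waypoint 1 and
contributes many fixes); grade below 2% in magnitude is `flat` — the flat
threshold is a design choice, as is the pooling radius.

Obstacle seconds (and the seated block) come from the course configuration
or a user event table: they are known by schedule, as they were in the
study design this emulates; no waveform-based obstacle detector is
implemented.  Gait crossed with slope, with events overriding, yields the
nine composite activities; seconds classified `other` outside any event
stay unlabelled.

## Fatigue labels

Scores are min–max normalized over the protocol, so the label tracks
normalized performance with **1 = freshest**.  "Predicting fatigue" here
means predicting performance decline; a flag inverts the polarity if 1 =
most fatigued is preferred.  Two label constructions:

- **LTLF** — the OLS line through normalized (time, score), evaluated on
  the 250 Hz grid and clipped to [0, 1].  Appropriate when the protocol
  guarantees constant hourly load.
- **ITI** — piecewise-linear interpolation through consecutive normalized
  observations, constant outside the observation span.  Retains short-term
  fatigue and recovery, needed when no load assumption can be made.

The ITI label itself is continuous across activity transitions; the
discontinuities visible in time-ordered prediction traces arise from
*windowing*, where non-adjacent segments of one activity are concatenated.
The default label source is the dominant-hand finger-tap test (the most
protocol-sensitive test of the battery); it is selectable.

Sensitivity of each test is the squared Pearson correlation of score
against time, optionally per assessment phase.  Outlier handling — known to
matter for Stroop — is implemented as an optional absolute studentized
residual threshold (default 3) rather than a manual judgement, so removals
are reproducible and logged in the result.  Whether normalization should
precede or follow outlier removal is undocumented in the source analysis;
here outlier screening operates on raw scores before any normalization.

## Windowing and the network

Per activity, all 250 Hz samples are concatenated in time order and cut
into `D = floor(N/W)` non-overlapping windows.  Windows may span seams
between non-adjacent segments; a strict mode breaks windows at seams but is
off by default because it changes the `floor(N/W)` accounting.  Channel
scaling is min–max per channel, fitted **on the training split only** and
reused for test windows — fitting on all data would leak label-correlated
range drift; a switch restores whole-data fitting for comparability.

The network is `Conv1D(n1) → Conv1D(n2) → max-pool(2) → flatten →
dense(nd) → dense(1)`, ReLU hidden activations, linear output, Adam on MAE.
Choices the source leaves open, fixed here as defaults: kernel size 7,
stride 1, same padding, pool size 2, Adam at its standard 1e-3 step size,
He initialization with zero biases.  Two study-scale presets ship —
`cnn_spec_initial()` (256/256 filters, dense 128, 50 epochs: the sweep
topology) and `cnn_spec_final()` (128/128, dense 128, 100 epochs: the
optimized topology) — but the package default is a desk-scale 16/16/32
network (35k parameters), which trains in minutes on one CPU and is already
sufficient to recover the synthetic fatigue signal.  The four channels
enter one multi-channel stack; a per-channel-branch variant was considered
and rejected as strictly more parameters for no gain at this scale.

The train/test split is a uniformly random window-level partition
(fraction 0.33).  Splitting windows randomly leaks temporal autocorrelation
between adjacent windows into the test set; it is implemented this way
because that is the procedure being reproduced, and a blocked-split mode is
provided for honest generalization estimates.  Training is fully seeded
(init and shuffling); the per-epoch loss trace records the running mean
over minibatches and the exact full-train MAE is computed once at the end.

The implementation is im2col + BLAS matrix multiplication with small C++
kernels for the im2col gather/scatter, fused bias+ReLU, and the pooling
pair; gradients are verified against central finite differences in the test
suite.  One numerical subtlety: with zero-initialized biases, convolution
outputs fed only by dead (all-zero) activations sit exactly on the ReLU
kink, so finite-difference checks must jitter the biases first.

## Evaluation

Test-set predictions are re-sorted into time order (the random split
destroys it), smoothed with an unweighted rolling mean of `k` predictions,
and compared against the window label at the centre of each rolling block —
centre alignment minimizes lag bias; the alignment convention is this
package's choice.  Metrics: `MAE_k` (mean absolute error) and `RAE_k`.
"Range of absolute error" admits two readings; since its purpose is the
largest error to expect from a future rolled estimate, the default is
`max |e|`, with `max − min` available as `rae_mode = "span"`.  One rolled
estimate spans `k · W / 250` seconds — 102.4 s at the standard `k = 200`,
`W = 128`.  Activities with fewer than `k` test windows are excluded and
reported as such rather than erroring the run.  Metrics are computed on the
test split only; computing them on all windows is the other defensible
reading and is not the default.

Constant-predictor baselines anchor every accuracy claim: a model is only
credited with learning if it beats the training-label-mean predictor.  For
the permutation null (shuffled labels must yield no skill) the reference is
instead the training-label *median*: under MAE loss a no-signal model
converges to the label median, which genuinely beats the mean constant on
skewed label distributions — comparing against the mean there would flag
"skill" that is only distributional skew.

## Problem sizes and reproducibility

The shipped checks use desk-scale sizes chosen as a deliberate trade-off:
a 4-lap default session (about 3.3 h, 1.2 M accelerometer and 3 M ECG
samples) for the end-to-end recovery experiment, with the rolling length
scaled to `k = 50` so the test split of one activity yields many rolled
estimates; 2-lap sessions for stage-level tests; 100 training epochs at
batch 256 for the recovery run and 30-epoch refits for the five-seed
permutation null.  On one CPU the full acceptance script runs in under ten
minutes.  Every stochastic step takes an explicit seed, and
`run_pipeline()` writes a manifest with the configuration hash and seeds so
any artifact can be traced to its inputs.

## Known limitations

- The generator's fatigue hooks (amplitude scaling, jitter growth, HR
  drift) are stylized; effect sizes on real gait are not calibrated to any
  dataset.  Results quantify pipeline correctness and statistical
  behaviour, not field accuracy.
- The random window-level split overstates test accuracy on autocorrelated
  signals (see above); use `blocked = TRUE` for generalization estimates.
- Cadence-based labelling cannot distinguish activities with similar
  cadence but different mechanics (e.g., stair climbing), and the 5 s
  window blurs transitions by a couple of seconds.
- LTLF assumes monotone-in-time fatigue; with within-hour recovery enabled
  in the trajectory, ITI is the only faithful label.
- Single-subject design: nothing here addresses inter-person variability;
  models are per-person by construction.
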