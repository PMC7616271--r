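---
title: "From 3D key-point tracks to behavioural metrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 3D key-point tracks to behavioural metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wagtrack turns multi-camera 3D key-point tracking of freely moving dogs into
trial-level behavioural response variables for a 2 × 2 within-subject design
in which the owner's and a stranger's presence in a 6 × 7 m testing room are
crossed. This vignette explains the processing model, the metrics, the
synthetic study generator the package tests itself against, and the design
decisions that were genuinely open.

```{r setup, message = FALSE}
library(wagtrack)
```

## The data model

Eight anatomical key points — snout, head centre, both ears, atlas, hips,
tail base and tail tip — are tracked per video frame at 24 fps and
reconstructed to metric 3D coordinates in a room-aligned, right-handed frame
with z up and the origin at a floor mark near the room centre. The floor
spans x ∈ [−3, 3] and y ∈ [−3.5, 3.5]. Each 120 s trial therefore yields up
to 2880 frames × 8 key points of (x, y, z) detections, with missingness
wherever reconstruction failed. `kp_trajectory()` stores one dense frame
grid per trial with `NA` rows for gaps; gaps are never encoded as zeros.

`room_geometry()` carries all spatial reference data: floor rectangle,
1.5 m height cap, two door landmarks and two chairs (chair A between the
doors, chair B on the opposite wall), four object planks near the room
centre, the interest areas (IAs) and the 0.5 m coverage grid. The chair IAs
measure 2 × 1.4 m and the door IAs 1 × 1 m; those dimensions are invariants
enforced at construction, while the chair and object positions are
configuration, not code — the defaults place the chairs at the middle of the
long walls and the planks equidistant around the centre, and can be
overridden from a YAML/JSON file via `read_geometry()`.

## The cleaning cascade

Raw reconstructions contain characteristic artefacts: points far outside the
room, single key points captured on the wrong object (a shoe tip detected as
the snout), and teleport jumps. `preprocess_trial()` applies, in order:

1. **Trial clipping** to `[onset, onset + 2880)` frames, re-based to zero.
2. **Bounds filter**: remove detections with (x, y) outside the floor or
   z above 1.5 m. All cascade thresholds are strict (`>`), so a point at
   exactly 1.5 m is kept.
3. **Centroid filter**: per frame, remove key points more than 1 m (3D) from
   the mean of the key points detected in that frame. The mean uses detected
   points only — the only computable choice under missingness. A frame with
   a single detection is never removed (its distance to its own mean is 0).
4. **Neighbour-jump filter**: remove detections that differ by more than
   1.5 m *per axis* from the temporally adjacent detections. "Per axis" is
   the literal reading of deviation "in any dimension", and is used
   identically in the velocity filter. The default is *spike* semantics — a
   detection is removed only when it deviates from **every** adjacent
   detection it has — because OR-semantics would delete both endpoints of
   any genuine fast displacement, which is incompatible with this filter
   removing only ~0.1 % of data in practice. `filter_config(neighbour_mode
   = "strict")` switches to the OR reading.
5. **Linear interpolation** of interior gaps per axis. No extrapolation:
   leading and trailing gaps stay missing, and a `max_gap` option (default
   unlimited, the literal reading) can cap the bridged gap length.
6. **Iterated velocity filter**: flag the later frame of any consecutive
   pair differing by more than 0.4 m per axis (9.6 m/s at 24 fps), remove,
   re-interpolate; four passes in total. Flagging the *later* frame is a
   deterministic, causal tie-break.
7. **Rolling average** over a centred 3-frame window, shrinking to the
   available frames at the boundaries of the covered span.

Every stage logs its removals per key point into a data-loss ledger, and the
ledger is conservative by construction: input detections = retained +
removed, summed over stages. The *proportion tracked* per key point is the
count of retained (never-interpolated) detections over the 2880 trial
frames; metrics use all valued frames (retained or interpolated) and report
their coverage, so denominators are always auditable.

## The behavioural metrics

All computed by `compute_trial_metrics()` from the processed head-centre,
snout, atlas, tail-base and tail-tip series:

* **IA occupancy** (owner IA, stranger IA, and the sum of the two door
  IAs): fraction of valued head-centre frames inside the rectangle.
  Rectangles are closed on their lower edges and open on their upper edges
  so that abutting areas never double-count. The primary denominator is
  valued frames; total trial frames is the auditable alternative via the
  reported coverage.
* **Distance travelled**: summed 3D displacement of the head centre between
  consecutive valued frames. The data are 3D, so the vertical component is
  included by default; `planar = TRUE` restricts to the floor plane.
* **Average minimal object distance**: mean over the four planks of the
  minimum horizontal distance from the head centre; plank centres at floor
  level are the reference points since the objects sit on the floor.
* **Area covered**: visited cells over total cells of a 0.5 m grid anchored
  at the floor's minimum corner (168 cells for the default room).
* **Visual angle**: the gaze is the head-centre→snout axis elevated by 45°
  within the vertical plane containing it, from an eye at the key-point
  midpoint; the metric is the mean per-frame 3D angle between that gaze and
  the direction to the owner's chair seat (default height 0.5 m,
  configurable — only the chair itself is anatomically determined). If the
  head axis is vertical the rotation plane is undefined and the frame is
  skipped and counted.
* **Tail-wagging ratio**: arc length of the tail tip over arc length of the
  tail base; 1 means the tail only followed the body.
* **Tail angle**: signed planar angle between the atlas→tail-base axis and
  the tail-base→tail-tip axis, positive toward the animal's right. With the
  body axis pointing backwards, `atan2(u×v, u·v)` yields exactly that sign
  convention for any heading, and mirror-reflecting a scene negates the
  angle exactly — a property the test suite exploits.

All metrics are invariant under rigid rotations/translations of the whole
scene, and only the tail angle changes (sign) under reflection.

## The synthetic study generator

Because the real tracked dataset is external, the package carries a
generator that emulates the *structure* of the study: `simulate_study(n)`
gives every dog one 120 s trial in each of the four conditions, rotates
deterministically through all 24 condition-order permutations (with 24 dogs
each order occurs exactly once), alternates the owner's chair, and returns
morphometry (matched exactly by the skeletons), C-BARQ subscale scores and
manual IA scorings alongside the trajectories.

The movement model is a goal-directed persistence walk, written in C++ for
speed but driven by R's RNG so a seed fixes everything. The walker samples a
current goal landmark with probability proportional to condition-dependent
attraction weights (a present person's chair is attractive; the doors
attract when somebody is absent; the novel objects always attract), heads
there with heading persistence and directional noise, pauses often near the
goal, and re-samples the goal after a mean dwell of 6 s. Two numerical
choices matter:

* the heading can rotate by at most 0.25 rad per frame. Key points sit up to
  ~0.7 m from the body centre, so a rate-limited heading bounds every
  per-frame key-point displacement well below the 0.4 m velocity threshold —
  a clean trajectory must pass the cascade untouched, and an earlier design
  that reflected the heading instantaneously at walls violated exactly that;
* walls are handled by a smooth avoidance push plus position clamping at a
  0.7 m margin, which also guarantees that the whole assembled body,
  including the swinging tail, never leaves the room.

The skeleton is rigid around position and heading (the snout sits exactly
the dog's measured snout–head distance from the head centre, which is what
makes the morphometry validation exact on clean data), and the tail tip
swings about a lateral bias angle (default +19°, the rightward asymmetry
scale reported for dogs near positive stimuli) with larger amplitude when a
person is present. Each trial's realized bias jitters by SD 2° around the
dog's own bias (drawn with SD 5° around the population value): without
within-dog variance the tail-angle mixed model would be degenerate.

Speeds are 0.5 m/s baseline, +0.25 m/s with the owner present, +0.12 m/s
with the stranger, −0.04 m/s per later trial (habituation), times a per-dog
log-normal factor (SD 0.12). None of these are estimates of real dog
kinematics — no quantitative movement statistics were available to fit — but
they are chosen once, at realistic orders of magnitude (total path lengths
of roughly 60–130 m per 120 s trial), and produce the qualitative
condition contrasts the analysis stage must detect.

`corrupt()` then injects the artefact families the cascade targets, each
bookkept per detection: dropout (default 5 %), teleports far outside the
room (0.2 %), ~2–2.5 m single-key-point glitches (0.2 %), single-axis
0.5–1 m jumps (0.4 %) and 1 cm isotropic jitter. Ground truth (true IA
occupancy, distance, coverage, tail angle, and the corrupted indices) is
computed inside the generator from its own state, so the metrics and
preprocessing modules can be tested for recovery rather than merely for
self-consistency.

What the generator does *not* emulate: occlusion-driven, spatially
correlated missingness; posture changes (sitting, lying); reunion
behaviour at doors; reprojection-error structure; or any fitted
correspondence to the real dataset. Passing tests therefore demonstrate
that the pipeline measures what it claims on data with known truth — not
that any particular biological effect size is reproduced.

## The validation battery

`tracking_summary()` reproduces the per-key-point proportion-tracked table
(median/min/max across runs, pooled mean reprojection error when the tables
carry one). `keypoint_distance_correlations()` checks that locomotion
estimates agree across key points — on simulated studies all torso/head key
points correlate above 0.98 while the tail tip, which moves partly
independently, sits around 0.8. `head_snout_distance_check()` compares the
per-dog *median* reconstructed head–snout distance (medians being robust to
residual outliers) with the measured one; on clean data the correlation is
exactly 1 by skeleton rigidity. `manual_vs_tracking_correlation()`
correlates tracking-based IA durations with manual scorings per IA type;
with the generator's scorer noise of SD 0.5 s all three correlations exceed
0.97. Pearson p-values are two-sided from the t transform with n − 2 df.

## The statistics scaffolding

Proportion-type responses are prepared for beta regression by max-scaling
and the boundary squeeze y″ = (y′(n − 1) + 0.5)/n, which keeps values
strictly inside (0, 1) and is exactly invertible. Condition models include
owner presence, stranger presence and their interaction plus trial number,
age and sex (trial and age centred and scaled to SD 1; reference categories
absent/absent/female), with a per-dog random intercept and, when requested,
random slopes for owner, stranger and trial. Gaussian responses (log
distance, log object distance) are fitted with `lme4::lmer` under ML;
proportions with a beta-family GLMM via `glmmTMB`. Requesting a beta family
from the lme4 backend is an explicit error, never a silent fallback.

On convergence failure the model is pruned in a fixed, recorded order: drop
the trial random slope, drop sex, drop age, drop the condition random
slopes. With 37 dogs × 4 trials the full random-slope structure has as many
random effects as observations, so the first rung typically engages — the
ladder is a feature of the design, not an error path. Inference is by
full–null likelihood ratio test (the null keeps controls and random
effects), per-term single-deletion LRTs with a Wald fallback when a deletion
refit fails, and VIFs computed from the closed form 1/(1 − R²).

Model weights default to the proportion of tracked data itself (better
tracked ⇒ more weight); because "weighting on the inverted proportion" can
be read three ways, `model_weights()` also offers `1 − p` and `1/p` behind a
switch rather than hard-coding one interpretation. The tail-angle model is
instead weighted by the tail-wagging index (the wag ratio max-scaled to
[0, 1]), concentrating inference on trials where the tail actually moved.
C-BARQ subscale scores are correlated with the IA occupancies per condition
and Holm-corrected across the whole family (`p.adjust`); with the
generator's independent scores the corrected table is empty of significant
entries, as it should be under the null.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the full study scale — 37
dogs, 148 runs of 2880 frames × 8 key points — through simulation,
corruption, the cascade and the metrics in well under a minute on one core;
Monte-Carlo checks use 20 seeds (effect recovery, tail-bias recovery,
occupancy monotonicity) or 100 seeds (null uniformity of the full–null LRT,
checked by Kolmogorov–Smirnov at α = 0.01, with the null data generated
directly at trial level). Every stochastic component draws from R's RNG
under an explicit seed; the C++ walker uses R's generator too, so whole
studies are bit-reproducible across platforms.

## Known limitations

* The beta-GLMM backend inherits glmmTMB's behaviour for weighted beta
  likelihoods; the weights scale the per-observation log-likelihood
  contributions and are not a variance model.
* The generator's manual scores share the trial clock with the tracking
  data; onset/offset scoring error is represented only as duration noise.
* `corrupt()` draws artefacts independently per detection; real detector
  failures cluster in time and space, so the cascade's measured efficacy
  (≈ 98 % of injected corrupt detections removed) is an upper bound relative
  to adversarially clustered noise.
* The occupancy denominator question (valued frames vs total frames) is
  resolved by reporting coverage alongside the primary choice, not by
  duplicating every metric.
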