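# wagtrack

Post-processing and behavioural metrics for multi-camera 3D key-point
tracking of freely moving dogs.

Markerless 3D tracking reconstructs eight anatomical key points (snout, head
centre, ears, atlas, hips, tail base, tail tip) of a dog exploring a 6 × 7 m
room, per frame at 24 fps, in metric room coordinates. Researchers studying
the *secure base effect* — the tendency of dogs to explore more in the
presence of their caregiver — need to turn those noisy reconstructions into
trial-level response variables for a 2 × 2 within-subject design crossing
owner and stranger presence. wagtrack implements that pipeline end to end:

* **Cleaning cascade** (`preprocess_trial()`): trial clipping; removal of
  detections outside the room or above 1.5 m; removal of key points more
  than 1 m (3D) from the per-frame key-point centroid; removal of per-axis
  jumps above 1.5 m against adjacent frames; linear gap interpolation; four
  passes of a 0.4 m-per-frame (9.6 m/s) per-axis velocity filter, each
  followed by re-interpolation; and a centred 3-frame rolling average — with
  a per-stage data-loss ledger and per-key-point proportions of tracked
  data.
* **Behavioural metrics** (`compute_trial_metrics()`): occupancy of the
  owner-chair, stranger-chair and door interest areas (2 × 1.4 m and
  1 × 1 m rectangles); distance travelled; average minimal distance to the
  four novel objects; proportion of a 0.5 m grid visited; the 3D visual
  angle between a 45°-elevated head–snout gaze and the owner's chair; the
  tail-wagging ratio (tip arc length / base arc length); and the signed 2D
  tail angle, positive toward the dog's right:

  tail angle = atan2(u × v, u · v), u = tail base − atlas, v = tail tip − tail base (floor plane).

* **Validation battery**: per-key-point tracking summaries, cross-key-point
  distance-travelled correlations, reconstructed-vs-measured head–snout
  distances, and tracking-vs-manual-scoring agreement.
* **Statistics scaffolding**: max-scaling with the boundary squeeze
  y″ = (y′(n − 1) + 0.5)/n for beta GLMMs (glmmTMB), log-transformed LMMs
  (lme4), tracking-quality observation weights, a fixed convergence pruning
  ladder, full–null likelihood ratio tests, VIFs and Holm-corrected C-BARQ
  correlations.
* **Synthetic study generator** (`simulate_study()`): a goal-directed
  persistence walk with a rigid articulated skeleton, lateralized tail
  oscillation, condition-dependent movement, counterbalanced designs and
  injectable detection noise with full ground-truth bookkeeping — so every
  stage is testable offline against known truth.

## Worked example

Simulate a small study, inject realistic detection noise, clean it, and
compute the response variables:

```r
library(wagtrack)

study   <- simulate_study(6, seed = 7)                       # 6 dogs x 4 conditions
noisy   <- preprocess_study(corrupt_study(study, noise_params(), seed = 8))
metrics <- compute_study_metrics(noisy)

head(metrics[, c("dog_id", "condition", "prop_owner_ia", "distance_travelled",
                 "area_covered", "mean_tail_angle", "prop_tracked_head_centre")])
#>   dog_id     condition prop_owner_ia distance_travelled area_covered
#> 1  dog01   both_absent        0.0517               80.4        0.512
#> 2  dog01    owner_only        0.0885              116.4        0.577
#> 3  dog01 stranger_only        0.0389               91.5        0.494
#> 4  dog01  both_present        0.0698              115.4        0.571
#> 5  dog02   both_absent        0.0326               59.7        0.387
#> 6  dog02    owner_only        0.1441               86.7        0.369
#>   mean_tail_angle prop_tracked_head_centre
#> 1            26.2                    0.931
#> 2            18.9                    0.932
#> 3            21.2                    0.931
#> 4            17.9                    0.930
#> 5            16.4                    0.926
#> 6            11.5                    0.940
```

Each row is one dog × condition: the dog in row 2 spent 8.9 % of tracked
frames in the owner interest area and walked 116 m in 120 s with its owner
present (vs 80 m alone), its mean tail angle of +18.9° indicates a rightward
wagging bias, and 93 % of its head-centre frames survived the filter cascade
as genuine (non-interpolated) detections.

Tracking-based interest-area durations agree closely with (simulated) manual
scorings, and the condition model recovers the generator's owner effect on
log distance:

```r
manual_vs_tracking_correlation(metrics, noisy$manual)
#>    comparison     r  n df        p
#> 1    owner_ia 0.997 24 22 4.44e-26
#> 2 stranger_ia 0.997 24 22 8.40e-26
#> 3     door_ia 0.972 24 22 2.25e-15

fit <- fit_condition_model(
  metrics, model_spec("distance_travelled", transform = "log",
                      weights = "prop_tracked", random_slopes = FALSE))
fit$coefficients[1:4, ]
#>              term estimate     se    z
#> 1     (Intercept)   4.1169 0.0583 70.6
#> 2    ownerpresent   0.4238 0.0295 14.4
#> 3 strangerpresent   0.3004 0.0295 10.2
#> 4         trial_z  -0.0572 0.0119 -4.8
fit$lrt
#> chisq = 58.44, df = 3, p = 1.26e-12
```

The owner coefficient (0.42 on the log scale, i.e. ×1.53) exceeds the
stranger's (0.30), and the full model beats the control-only null decisively.

See `vignette("trajectory-postprocessing")` for the processing model, the
generator's assumptions, and the design decisions.

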