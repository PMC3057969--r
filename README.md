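# pointkin

Kinematics and endpoint-variability analysis of communicative pointing
gestures.

## The problem

Pointing at an object *for somebody* is not the same movement as pointing at
an object for nobody. One behavioral window onto this difference is
**endpoint variability**: when a person points repeatedly at the same
target, the final fingertip positions scatter, and the shape of that 2D
scatter — summarized by a **tolerance ellipse**, the ellipse whose axes are
the eigenvectors of the endpoint covariance matrix — reflects the reference
frame used to plan the movement. If communicating with an addressee
recruits a reference frame linked to the addressee's position, the
orientation of the ellipse's long axis relative to the pointer's frontal
plane should rotate with the addressee's location (left vs right), and
differ from pointing with no addressee.

`pointkin` is for motor-control and social-cognition researchers who want
to run (or scrutinize) this analysis end to end, from raw 400 Hz
motion-capture marker streams to calibrated Monte-Carlo inference:

* **Kinematics** — exponential trajectory smoothing
  (`xx_i = xx_{i-1} + (x_i - xx_{i-1})·0.1`), tangential velocity, movement
  segmentation at 5% of peak velocity, rejection of multi-peaked
  (re-aimed) movements, temporal parameters (corrected reaction time,
  duration, time to peak, peak/mean velocity, distance) with
  repeated-measures condition ANOVAs, and 20-point time-normalized
  trajectories with per-point ANOVAs.
* **Endpoint statistics** — Cook's-distance outlier exclusion (cutoff
  0.25), per-participant 2×2 endpoint covariances, normalization by the
  first eigenvalue, across-participant average tolerance ellipses, and
  axial orientations θ ∈ [0°, 180°) vs the frontal plane, with axial
  differences min(|a−b|, 180−|a−b|).
* **Monte-Carlo inference** — the within-subject union-resampling test:
  for each subject, simulated condition samples of the original sizes are
  drawn with replacement from the pooled two-condition endpoints, average
  ellipses are rebuilt, and p = N/10000 counts simulated orientation
  differences at least as large as observed.
* **A synthetic-experiment generator** — minimum-jerk reaches with marker
  jitter, condition-dependent anisotropic endpoint scatter, the full
  balanced 30-block / 300-trial design, and a ground-truth sidecar, used by
  the validation studies in place of the unreleased raw data.

See `vignettes/pointing-endpoint-variability.Rmd` for the methods in full.

## Worked example

Simulate a 6-participant study of the central target, with the three
conditions' endpoint clouds configured at 72.8° (left-addressee CP),
112.7° (right-addressee CP) and 100.4° (no addressee), then analyze it:

```r
library(pointkin)

cfg <- generator_config(n_participants = 6, targets = default_targets()[1, ],
                        seed = 7)
ex <- generate_experiment(cfg)
an <- analyze_experiment(ex$trials,
                         run_config(n_permutations = 2000, rng_seed = 7))
print(an)
#> Pointing analysis
#>   trials: 360 ingested, 360 valid, 22 excluded endpoints (6.1% outliers)
#>   glass      LEFT_CP   average ellipse orientation   79.2 deg
#>   glass      NCP       average ellipse orientation   99.6 deg
#>   glass      RIGHT_CP  average ellipse orientation  105.1 deg
#>   endpoint_orientation   LEFT_CP vs NCP       diff  20.4 deg  p = 0.0035
#>   endpoint_orientation   LEFT_CP vs RIGHT_CP  diff  25.9 deg  p = 0.0005
#>   endpoint_orientation   NCP vs RIGHT_CP      diff   5.5 deg  p = 0.3475
#>   trunk_orientation      LEFT_CP vs NCP       diff   0.0 deg  p = 0.9975
#>   trunk_orientation      LEFT_CP vs RIGHT_CP  diff   0.1 deg  p = 0.656
#>   trunk_orientation      NCP vs RIGHT_CP      diff   0.1 deg  p = 0.669
```

Reading the output: every generated trial passed segmentation; Cook's
distance excluded 6.1% of endpoints; the recovered average-ellipse
orientations (79.2° / 99.6° / 105.1°) approximate the configured truths
with ~20 endpoints per participant and condition; the two communicative
conditions differ from each other and the left-addressee condition from
NCP, while the trunk control — generated with identical posture across
conditions — stays at fractions of a degree and non-significant, exactly
as it should. Axial arithmetic is available directly:

```r
axial_difference(72.8, 112.7)
#> [1] 39.9
```

## The analysis workflow

The numbered scripts under `analysis/` run the full simulated study
(10 participants × 300 trials) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # design balance + ground truth
Rscript analysis/02_fit.R          # full pipeline, all result tables
Rscript analysis/03_endpoints.R    # ellipse geometry vs configured truth
Rscript analysis/04_inference.R    # pairwise Monte-Carlo tests + trunk control
Rscript analysis/05_calibration.R  # type-I error and power curves
```

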