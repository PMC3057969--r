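---
title: "Kinematics and endpoint variability of communicative pointing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematics and endpoint variability of communicative pointing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pointkin)
```

## The scientific question

When a person repeatedly points at the same object, the final fingertip
positions scatter around the target, and the *shape* of that scatter is
informative: the covariance of the 2D endpoint cloud, drawn as a tolerance
ellipse, tends to elongate along directions that the motor system controls
least precisely, and its orientation has been read as a signature of the
reference frame used to plan the movement. `pointkin` implements an analysis
pipeline for exactly this question in the context of *communicative*
pointing: does pointing at an object **for an addressee** (left or right of
the pointer) reshape the endpoint scatter relative to pointing with no
addressee at all?

The pipeline takes raw multi-marker motion-capture recordings (fingertip,
button-state, and two shoulder LEDs at 400 Hz) through four stages:

1. **Kinematics** — trajectory smoothing, tangential velocity,
   velocity-threshold movement segmentation, temporal parameters
   (corrected reaction time `cRT`, duration `dur`, time to peak `ttp`,
   peak/mean velocity, distance) with condition ANOVAs, and 20-point
   time-normalized trajectories with per-point ANOVAs.
2. **Endpoint statistics** — per participant and condition, Cook's-distance
   outlier exclusion, the 2×2 endpoint covariance, size normalization by the
   first eigenvalue, and across-participant average tolerance ellipses with
   their axial orientations relative to the frontal plane.
3. **Monte-Carlo inference** — a within-subject union-resampling test for
   differences in average-ellipse orientation between condition pairs, with
   `p = N / n_sims`.
4. **Controls** — initial trunk orientation from the shoulder markers, with
   the same resampling test, to rule out postural confounds.

Because the original raw recordings are not publicly available, the package
ships a first-class synthetic-experiment generator with known ground truth;
every empirical claim the test suite makes is a claim about recovery of
configured truth or about statistical calibration, not a re-analysis of the
original data.

## The measurement model

**Smoothing.** Each marker coordinate is filtered with the recursive
exponential blend $xx_i = xx_{i-1} + (x_i - xx_{i-1})\,c$, $xx_1 = x_1$,
with coefficient $c = 0.1$ by default. A literal "two-tap" variant that
blends with the raw (not filtered) previous sample is available via
`filter_form = "two_tap"`; it delays by about one sample but provides almost
no noise attenuation, so the recursive exponential form is the default: at
400 Hz with ~0.05 mm marker noise, unsmoothed central differences produce
velocity noise of the same order as the 5% onset threshold and break
segmentation entirely.

**Velocity and segmentation.** Tangential velocity is the norm of the
centrally differenced (one-sided at the boundaries) filtered position,
scaled by the sampling rate. Movement onset is the first sample at which
velocity reaches 5% of its maximum, searched from the series start; the
offset is the first sample after the global maximum at which velocity drops
below that threshold again (the final sample, with a warning, if it never
does). Both thresholds are relative, so segmentation is invariant to uniform
velocity rescaling.

**Multi-peak rejection.** Trials whose velocity profile shows more than one
distinct peak above half of the maximum are flagged invalid (they
correspond to corrective or re-aimed movements). A peak is *distinct* only
if velocity dips below the half-max threshold between maxima — i.e. we
count threshold excursions, not raw local maxima. This distinction matters:
with realistic marker noise, the flat top of a bell profile carries several
strict local maxima within a few samples, and a raw local-maximum count
would reject essentially every trial. The excursion rule reproduces the
intended behavior on genuinely two-lobed profiles while remaining
noise-robust; the fraction (0.5) is configurable as
`peak_multiplicity_frac`.

**A known, condition-independent duration bias.** A causal exponential
filter attenuates and delays the velocity peak and convexly rounds the
profile near the threshold crossings, which *widens* the measured 5%-to-5%
span: at $c = 0.1$ and 400 Hz the widening is about 4–10 samples (10–25 ms)
for minimum-jerk reaches of 450–750 ms. No causal first-order smoother can
avoid this. The synthetic generator therefore records two ground truths per
trial: the *nominal* duration (the 5% span of the ideal continuous profile)
and the *measurement reference* (onset/offset obtained by applying the same
filter-velocity-threshold chain to the noiseless trajectory). Recovery tests
compare against the measurement reference, which isolates what they are
meant to quantify — robustness to marker noise and sampling discretization
(about ±1 sample) — from the deterministic filter bias, which affects all
conditions identically and cancels from every between-condition contrast.

## Endpoint statistics

**Outlier exclusion.** Following the protocol's influence-based rule,
each endpoint's Cook's distance is computed from an intercept-only fit per
coordinate (classical $D_i = (e_i^2/(p\,s^2))\,h/(1-h)^2$ with leverage
$h = 1/n$), and a point is excluded when the larger of its two per-axis
distances exceeds 0.25, in a single pass. The protocol names no regression
model for the Cook's step; the intercept-only model is the simplest one
consistent with "influence on the overall distribution", and a joint
bivariate Mahalanobis variant is available behind `cooks_method =
"mahalanobis"`. At the study's cell size (n = 20) and Gaussian scatter this
rule excludes about 4–7% of endpoints — consistent with the roughly 4%
exclusion the original protocol reports.

**Tolerance ellipses.** The unbiased 2×2 covariance of the kept (x, y)
endpoints is eigen-decomposed; the orientation is the axial angle (modulo
180°) of the dominant eigenvector against the x-axis (the horizontal trace
of the frontal plane). "First eigenvalue" normalization divides the matrix
by its largest eigenvalue — size is dominated by the major axis, and this
leaves orientation untouched while equating ellipse scale across
participants. Per-condition average ellipses are element-wise means of the
normalized matrices, decomposed afresh. Near-isotropic matrices
($\lambda_2/\lambda_1 > 0.999$) carry a `degenerate` flag; their
orientation is numerically defined but statistically meaningless, so they
are dropped from averages with a warning and abort an orientation test with
a diagnostic. The 95% tolerance-region scaling
($\sqrt{\lambda\,\chi^2_{2,0.95}}$ axes) is used only for drawing
(`ellipse_outline()`); no statistic depends on it.

**Axial arithmetic.** Ellipse orientations are undirected: all angle
handling is modulo 180°, differences are $\min(|a-b|, 180-|a-b|) \in
[0, 90]$, and means (used for trunk angles) double the angles, average unit
vectors, and halve back.

## The Monte-Carlo orientation test

For conditions $a$ and $b$, the observed statistic is the axial difference
between the across-subject average ellipses (each built from per-subject
normalized covariances). Under the null that each subject's two samples
come from one distribution, each iteration draws, for every subject
independently, $n_s$ and $m_s$ points with replacement from that subject's
pooled $a \cup b$ endpoints ($n_s, m_s$ = the subject's observed
per-condition counts, which differ after outlier exclusion), rebuilds both
average ellipses exactly as in the observed statistic (normalization
included), and records the simulated difference. With $N$ the number of
iterations at or above the observed difference (ties count),
$p = N/n_\text{sims}$ with $n_\text{sims} = 10{,}000$ by default; no $+1$
correction is applied, matching the printed form of the statistic.

Implementation notes, all verified in the test suite:

* The engine is vectorized across iterations with closed-form 2×2
  eigenstructure (trace/determinant quadratic and
  $\theta = \tfrac12\operatorname{atan2}(2\sigma_{xy},
  \sigma_{xx}-\sigma_{yy})$), cross-checked against `eigen()` to 1e-9.
  Pooled point sets are centered before the moment sums to avoid
  cancellation. A 10,000-iteration test on 10 subjects runs in ~0.3 s,
  which is what makes the 500-dataset calibration study tractable on one
  CPU. One seeded generator drives the whole test, with subjects processed
  in sorted order; identical seed and inputs give bit-identical `N`.
* Iterations that produce a rank-zero or degenerate ellipse (possible in
  principle when a with-replacement draw collapses) are redrawn, at most
  100 passes, and counted in the result — silently discarding them would
  bias `N`.
* **A power caveat inherent to union resampling:** when the two conditions
  are *exactly* orthogonal with equal anisotropy, the pooled union is
  isotropic, simulated orientations are nearly uniform, and the null spread
  of the difference covers the full [0°, 90°] range — the p-value plateaus
  around 1–3% even for the maximal observed difference. Power is therefore
  non-monotone at extreme separations; at the moderate separations relevant
  here (≤ 45°) it rises steeply with separation, as the calibration study
  shows.

## The synthetic-experiment generator

`generator_config()` describes a complete study; its defaults are the study
conditions: 10 participants; 3 conditions (left-addressee CP,
right-addressee CP, NCP); 5 targets in a cross arrangement 100 mm apart
with a round, isotropically placed central target; 20 repetitions per
target and condition in 30 blocks (10 per condition, condition order
cyclically counterbalanced across participants, each target exactly twice
per block in seeded random order); 400 Hz sampling.

Per trial, the fingertip follows a minimum-jerk polynomial from the start
position to an endpoint drawn from the condition's 2D Gaussian around the
target, with a modest vertical arc; the speed profile is single-peaked by
construction. The profile is time-scaled so that the *5%-threshold span* of
the ideal profile equals the drawn nominal duration (for threshold fraction
$f$ the span of a unit minimum-jerk profile is $\sqrt{1-\sqrt{f}}$ of its
support, ≈ 0.881 at $f = 0.05$). Button release (LED2 off) precedes
movement onset by a 20–60 ms gap to exercise the reaction-time correction;
stationary padding surrounds the movement; isotropic marker jitter
(SD 0.05 mm, matching a 0.1 mm-resolution tracker) is added to all markers;
shoulder markers place the trunk at a per-trial jittered but
condition-independent posture.

The per-condition endpoint models default to the published average-ellipse
orientations (72.8° for left-addressee CP, 112.7° for right-addressee CP,
100.4° for NCP) with eigenvalue ratio 0.25 and 8 mm major-axis SD. The
orientations are published values; the scatter magnitudes are not (raw
variances were never published), so the ratio and scale are modelling
choices producing ellipses of plausible anisotropy, and recovery tolerances
in the tests are quantified against them by simulation. Options exist for
far-field endpoint contamination (to exercise the outlier filter), for a
condition-dependent lateral/vertical trajectory bias ramp (off by default;
the positive control for the pointwise ANOVA), and for a condition-dependent
trunk rotation (zero by default, making the trunk control a true null).

What the generator does *not* emulate: addressee behavior, audio
instructions and naming responses (only their kinematic consequences),
biomechanical arm dynamics, within-session learning or fatigue drift, and
any structured (non-Gaussian, autocorrelated) tracker noise. Passing
recovery tests on this generator therefore demonstrates that the pipeline
measures what it claims under the stated noise model — not that the
original empirical effect is reproduced from real data.

## Problem sizes and numerical choices

The test suite's study-scale checks use: 10,000-endpoint clouds for
orientation recovery (±1°); 500 null datasets × 1,000 iterations for
type-I calibration (5% ± 2%); 50 replicates at the published three-condition
geometry for the dominance of the left-vs-right contrast; 1,000 random
bell-profile trials for duration recovery (≥ 95% within 2 samples, median
≤ 1 — a coverage statement, since threshold crossings under stochastic
marker noise have no worst-case guarantee); and brute-force summation
oracles at n ≤ 6 for covariance, eigenstructure, and Cook's distance
(1e-12). The analysis scripts under `analysis/` run the full 3,000-trial
simulated study; datasets are deterministic functions of the seed, so the
scripts regenerate rather than store them.

Other numerical decisions: resampled trajectory points sit at
$t_\text{onset} + k\,\text{dur}/20$, $k = 1..20$ (the last point coincides
with the offset sample), linearly interpolated — at 400 Hz the interpolation
error is far below the 0.1 mm marker resolution. Repeated-measures ANOVAs
are computed by `stats::aov` with an `Error(unit)` stratum on unit ×
condition cell means, where the unit is the participant (within-participant)
or the target (within-item); the degenerate zero-between-variance case is
resolved to F = 0, p = 1 before fitting. Trial files store doubles with 17
significant digits so write→read round-trips are bit-identical.

## Limitations

* The pipeline analyzes the horizontal (x, y) projection of endpoints only,
  matching the protocol; no 3D ellipsoid analysis is provided.
* The Cook's-distance model, the multi-peak excursion rule, and the
  degenerate-ellipse policy are principled reconstructions of steps the
  protocol describes only loosely; each is configurable and its choice is
  documented above.
* The union-resampling test's power loss at near-orthogonal separations is
  a property of the published procedure itself, not of this implementation.
* Reported p-values are Monte-Carlo estimates with SE
  $\sqrt{p(1-p)/n_\text{sims}}$; at the default 10,000 iterations a true
  p of 0.02 is estimated to about ±0.0014.
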