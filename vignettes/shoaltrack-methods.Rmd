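---
title: "Methods: trajectory cleaning, behavioural metrics and the null-model comparison"
author: "shoaltrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory cleaning, behavioural metrics and the null-model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoaltrack)
```

# Overview

`shoaltrack` analyses groups of fish filmed from above in circular
open-field arenas and tracked by multi-animal video software. The pipeline
has five stages:

1. **Ingestion** of per-frame, per-individual x,y coordinate tables
   (`read_track_table()`), with missing detections preserved as `NA`.
2. **Cleaning** (`preprocess_trial()`): normalization to an arena-centred
   cm frame, deletion of physically impossible points, and interpolation
   of short tracking gaps.
3. **Behavioural metrics** (`build_behavioural_profile()`): seven
   variables per fish covering activity, arena use and sociality.
4. **Null model** (`run_null_model()`): an interaction-free
   correlated-random-walk simulation with empirically sampled kinematics,
   against which real group structure is judged
   (`compare_real_vs_sim()`).
5. **Statistics** (`zscore_profiles()`, `pca_varimax()`,
   `fit_condition_lmm()`, `levene_variance_test()`): varimax-rotated
   principal components of the seven variables and mixed-model condition
   contrasts with a batch random effect.

A synthetic-data module (`generate_school()`,
`inject_tracking_artifacts()`, `generate_cohort_for_pca()`,
`generate_comparison_cohort()`) produces schooling trials with known
latent behaviour and tracker-like corruption, so every stage is testable
without video data.

# The reference recording geometry

The defaults describe a 29 cm circular arena imaged at 1000 px across
(0.029 cm/px), recorded for 60 min at 25 Hz (90,000 frames) with groups of
10 fish. The arena radius is therefore 14.5 cm in the normalized frame.
Two unit conventions matter throughout:

* **Speeds** are computed per frame (cm/frame) and reported per second
  (cm/s = cm/frame × 25).
* **Stillness** is defined at the pixel scale: a fish that moved less than
  one pixel (0.029 cm) between frames is still. Restated per second this
  is 0.725 cm/s, conventionally rounded to 0.7 cm/s.

The reference protocol quotes both 0.03 cm per pixel and a 1000-pixel
(29 cm) diameter, which disagree by 3%; we take the diameter as operative
(0.029 cm/px), and both numbers are configurable via `arena_geometry()`.
Similarly, the 3 cm edge zone is described as 20% of the radius, which
implies the physical 15 cm radius of the 30 cm arena rather than the
14.5 cm normalized radius; we keep 3 cm as the operative width.

# Cleaning

Cleaning applies three steps in a fixed order, and the chain is
idempotent (a second pass changes nothing):

1. **Out-of-arena deletion.** Radial distance greater than the arena
   radius marks a reflection of the fish detected on the arena wall; the
   point becomes missing.
2. **Speed filter.** Steps faster than a maximum possible swimming speed
   (0.91 m/s) indicate identity confusion. The *later* point of an
   offending pair is deleted and speeds are recomputed on the fly, so one
   erroneous detection cannot erase its valid neighbours: within a run of
   consecutive raw violations only every other point is removed.
3. **Gap interpolation.** Missing runs strictly shorter than one second
   (24 frames or fewer at 25 Hz) that are flanked by five valid frames on
   each side are filled with the least-squares cubic polynomial fitted to
   those ten flanking frames, x and y independently against frame index.
   A cubic reproduces straight-line and cubic-polynomial paths exactly,
   which is the natural reading of fitting "the polynomial that best
   approximates" the gap. Two guards keep the chain stable: filled points
   outside the arena are radially clamped just inside the wall, and a
   fill whose steps would break the maximum-speed rule (for example a
   bridge across an unresolved identity swap) is rejected, leaving the
   gap missing.

The five-frame context is used both as the eligibility condition and as
the fitting window; the fit is a degree-3 least-squares polynomial, exact
when ten points are available and never underdetermined for the minimum
context of two frames per side.

# The seven behavioural variables

For each fish (or pooled per trial):

| variable | meaning | units |
|---|---|---|
| `median_speed` | median instantaneous speed | cm/s |
| `prop_still` | fraction of frame pairs moving < 1 px | proportion |
| `prop_near_edge` | time within 3 cm of the wall (thigmotaxis) | proportion |
| `time_to_explore_10pct` | latency to enter 10% of grid cells | s |
| `pct_arena_explored` | fraction of grid cells ever entered | proportion |
| `median_nn_distance` | median distance to the closest group-mate | cm |
| `mean_local_neighbour_prop` | mean share of the group within the local-neighbour radius | proportion |

The exploration grid partitions the arena into 1 × 1 cm squares with the
grid origin at the arena centre on a cell corner; a cell belongs to the
grid when its square overlaps the disc with positive area. For the
default geometry this yields 724 cells (verified against a brute-force
rasterization). No corner-aligned convention reproduces the 788 cells
reported for the reference arena — its grid alignment is not
documented — so the convention and the resulting count are configurable
and always logged. The 10% milestone is `ceiling(0.10 * n_cells)` whole
cells.

The local-neighbour radius is the median of all pairwise inter-fish
distances pooled over the dataset (`dataset_neighbour_radius()`); 6.9 cm
in the reference dataset, recomputed from the data at hand otherwise.
Frames in which a fish is missing are excluded from that fish's
denominators, and pairs with a missing member are excluded from distance
pools; no imputation happens beyond the gap interpolation above.

The seven variables are invariant under rotation of the coordinates about
the arena centre, except that grid-based coverage is only approximately
so (the grid itself is square); the test suite asserts exact invariance
for the five non-grid variables and approximate invariance for coverage.
Missing exploration latencies (a fish that never reached 10%) are imputed
as the full trial duration before z-scoring — a conservative censoring —
and the number of imputed values is recorded.

# The null model

The null model asks what group-level statistics arise from arena geometry
alone. Independent agents move by

x(t+1) = x(t) + v(t) cos(θ(t) + ω(t)),  y(t+1) = y(t) + v(t) sin(θ(t) + ω(t)),

with the heading advancing to θ(t) + ω(t), and v, ω drawn uniformly with
replacement from pools of per-frame speeds and wrapped heading changes
harvested from observed trajectories (`harvest_pools()`). Headings are
measured as `atan2` of successive displacements; sub-pixel steps have no
defined heading and contribute no ω. A step that would leave the arena is
replaced by its radial mirror about the boundary circle (r → 2R − r at
the same polar angle).

Choices the update equations leave open, and how we resolved them:

* **Heading recursion.** θ(t+1) = θ(t) + ω(t) — the only reading under
  which ω is an angular speed.
* **Reflection and heading.** By default a reflection moves the position
  only; the next ω draw is independent anyway. `reflect_heading = TRUE`
  mirrors the heading about the local wall tangent (billiard bounce),
  which matters only for degenerate pools: with ω ≡ 0 an unreflected
  heading walks the agent into the wall and keeps it there, while the
  billiard variant yields straight segments between rare reflections and
  a realized median speed exactly equal to the coded one.
* **Initial conditions** (not fixed by the protocol): positions
  uniform in the disc, headings uniform in (−π, π].
* **Reproducibility.** Each replicate runs on its own substream derived
  from the master seed.

One known limitation: pools harvested from *simulated* trajectories
inherit apparent turns created by boundary reflections, so a null model
fed such pools is slightly more tortuous than its source. The
null-equivalence test therefore feeds the null model the generative step
distributions directly.

`compare_real_vs_sim()` fits, for each of the five variables not directly
encoded in the model (edge use, exploration latency, coverage,
local-neighbour proportion, nearest-neighbour distance), a linear model
with the simulated arm as reference — the estimate is real minus
simulated — plus a median-centred Levene (Brown–Forsythe) test of
variance homogeneity.

# Statistics

The seven variables are z-scored and decomposed by PCA on the correlation
matrix; the top three components (the customary choice for these data,
configurable) are rotated with Kaiser-normalized varimax. Each rotated
component is flipped so its largest loading is positive and components
are ordered by explained variance. Scores use the regression method.
Orthogonal rotation preserves communalities but does not guarantee
uncorrelated scores, so the score correlation matrix is reported rather
than assumed diagonal.

Condition effects on component scores are tested with linear mixed
models: condition as a categorical fixed effect (reference level
"ambient") and a random intercept for batch, since arenas are recorded
several at a time. p-values use the Satterthwaite approximation; if that
machinery fails the model falls back to a normal approximation, and a
zero-variance response falls back to ordinary regression with a warning —
never a crash. Fish within a trial share their group's history, so for
condition inference the trial mean score is the appropriate unit; the
acceptance script averages fish-level scores per trial before fitting.

# The synthetic-data generator

`generate_school()` extends the null-model update with a deliberately
minimal social kernel. Each frame, a fish's heading change is

ω = N(0, turn_sd) + attraction · wrap(bearing to group centroid − θ)
  + wall_bias · wrap(wall direction − θ),

and its speed is 0 with probability `stillness_prob`, else exponential
with mean `speed_scale`. The wall direction is the local tangent, taken
in a single circulation sense shared by the trial and tilted outward;
speeds, arena and reflection are exactly as in the null model. Latent
parameters may be per-fish vectors, giving individual variation within a
group.

Three design details were settled empirically while building the
generator, because the first-try kernel confounded the latent axes:

* **Common circulation sense.** With each fish following whichever
  tangent sense was closer to its heading, wall-followers met head-on and
  sheared schools apart, so wall bias destroyed cohesion. Milling schools
  adopt a common rotation direction; with a shared per-trial sense,
  wall-following and cohesion coexist.
* **Radially dominated wall direction.** A mostly tangential wall pull
  made cohesive schools and wall-following mutually destructive (the
  school's centroid attraction fought the sweep along the wall). Tilting
  the wall direction outward lets a cohesive clump simply sit at the
  wall. Single trials default to a moderate tilt; the planted-factor
  cohort uses a strong tilt.
* **Stratified near-orthogonal latent design.** With 26 trials, plain
  uniform draws of the three latents show chance correlations up to
  ~0.5, blurring any planted factor structure. The cohort generators
  instead use equally spaced latent levels permuted to minimize pairwise
  correlation — a small near-orthogonal experimental design.

`generate_cohort_for_pca()` varies attraction (sociability), wall bias
(boldness) and an activity score (mapped to stillness probability and a
modest speed range) independently across 26 trials of 10 fish, split
9 + 9 + 8 across three pseudo-conditions that interleave across batches
of three (arenas recorded simultaneously hold different conditions; with
conditions nested in batches instead, the mixed-model contrasts were
measurably conservative). The default ranges — attraction 0–0.2, wall
bias 0–0.06, stillness 0.40→0.26, speed 0.14→0.16 cm/frame — were chosen
once, while designing the generator, so that each latent axis expresses
itself dominantly in its intended variables: wide attraction variation
drives cohesion *and* coverage, while activity variation is kept modest
enough that coverage remains primarily a sociability readout. Trait
cross-talk is physical, not numerical: exploration latency responds to
all three latents, and with only 26 trials the varimax cross-loadings
fluctuate by roughly ±0.1 between cohort draws. The planted-block
recovery test fixes the package-default seed; across a dozen evaluation
seeds the three axes always separate with own-block loadings above 0.75,
while the stricter off-block bound (< 0.3) holds at most but not all
seeds.

`generate_comparison_cohort()` is the counterpart for the
real-versus-null comparison: every group is at least moderately social
(attraction 0.08–0.2), wall bias spans 0–0.15, and — crucially — each
fish's gains are scaled by an individual factor uniform on 0–2. Without
individual variation the null-model arm is *more* variable in edge use
and nearest-neighbour distance than the synthetic fish (independent
wanderers spread widely; group-locked fish do not); with it, the
synthetic "real" arm is more variable in all five compared variables,
which is the qualitative signature of real fish against a memoryless
model.

`inject_tracking_artifacts()` corrupts clean trials with the three
tracker error modes — missing-detection gaps (1–40 frames), reflection
spikes at radius (R, 1.2R] on the same polar angle, and identity swaps
over short stretches — and returns a ground-truth ledger that exactly
describes the corruption (gaps are kept disjoint for this reason).

# Problem sizes and test design

Synthetic trials default to 9,000 frames (6 min at 25 Hz), a size at
which every metric is estimated well while a full 26-trial cohort builds
in well under a minute; full-length 90,000-frame runs are available by
argument. The test suite checks every metric against naive brute-force
oracles on small trials (≤ 3 fish × ≤ 100 frames), property-style
invariants (rotation and relabelling invariance, idempotent cleaning,
arena containment, monotone coverage) on generated cases with fixed
seeds, mixed-model calibration on simulated scores (500 cohorts), a
full-pipeline type-I check across 30 reduced cohorts, and power > 0.8
for a planted +0.2 attraction shift at 4,000 frames with the trial as
the analysis unit.

What passing these tests shows — and what it does not: the synthetic
schools reproduce the qualitative structure of real groups (cohesion,
thigmotaxis, activity variation, tracker artifacts) but not fish
biomechanics (no body axis, no burst-glide kinematics, no hydrodynamic
interaction), no depth dimension, and no condition-specific physiology.
Results on synthetic cohorts validate the *pipeline* — its bookkeeping,
estimators, calibration and power — not any biological claim about real
fish.

# Known limitations

* The exploration grid count (724 cells) reflects our stated convention;
  the reference count (788) is not reproducible from any corner-aligned
  convention and the original alignment is undocumented.
* Harvested movement pools conflate behaviour with boundary-reflection
  artifacts near the wall (see above).
* Between-trial latent variation makes fish-level condition inference
  pseudo-replicated; use trial-level units (or add a trial random effect)
  for condition contrasts.
* Equivalence testing of "no condition difference" (TOST) is not
  implemented; the mixed models report contrasts and their uncertainty
  only.
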