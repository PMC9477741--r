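---
title: "Quantifying villus lymphocyte motility: metrics, preprocessing and the two-state simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying villus lymphocyte motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villustrack)
```

## The scientific problem

Group 3 innate lymphoid cells (ILC3s) of the intestinal mucosa are largely
immotile at steady state, but acquire a migratory "patrolling" behavior under
inflammatory signals, T-cell deficiency, or altered chemokine availability —
a switch that matters for IL-22 delivery and epithelial integrity. Intravital
two-photon imaging quantifies this switch with a small set of per-cell track
statistics. This package implements those statistics, the preprocessing
conventions used on intravital movies of the gut, and a generative stand-in
for the movies themselves, so the whole analysis can be exercised, validated
and taught without raw imaging data.

## Per-track metrics

All computation starts from a `track`: one cell's ordered positions, in
micrometres, at (nominally) fixed frame intervals in minutes. Units are fixed
package-wide — µm, minutes, µm/min — because that is how cohort motility
statistics are conventionally reported for tissue lymphocytes.

* **Instantaneous speed**: Euclidean displacement between consecutive
  observed positions divided by the actual time difference. Steps spanning a
  tolerated acquisition gap are excluded rather than interpolated.
* **Arrest coefficient**: the percentage of steps with instantaneous speed
  *strictly below* 3 µm/min. The strict inequality is deliberate: a step at
  exactly the threshold counts as motile. With uniform frames, counting steps
  is an exact "percentage of time". Stored as a percentage (0–100).
* **Straightness ratio**: net displacement over path length, in [0, 1]. A
  zero-length path makes the ratio undefined; it is reported as missing, not
  coerced to 0 or 1.
* **Mean squared displacement (MSD)**: for lag $n\,\Delta t$, the mean of
  $|r_{i+n}-r_i|^2$ over *all overlapping index pairs* within uniformly
  sampled stretches of the track. Long lags are estimated from few intervals
  and are noisy, so the default maximal lag is half the track length and the
  number of contributing intervals is reported per lag so users can truncate
  further. The cohort MSD averages *tracks*, not intervals: every cell
  contributes equally regardless of its track length, matching per-cell
  plotting, and lags supported by fewer than a configurable number of tracks
  (default 10) are dropped.
* **Speed over time**: all instantaneous speeds of a cohort pooled into
  wall-clock bins relative to a treatment event, reported as mean ± s.e.m.
  with the pooled step count; empty bins are omitted.

Two behavioral calls are layered on the metrics. A cell is **arrested over
its track duration** if its arrest coefficient is at least 80%. A track is a
**"spot"** (restricted, in-place) if its net displacement is below 10 µm *or*
the cell is arrested, and **"wavy"** (extended, meandering) otherwise. The
published dichotomy was visual; these numeric surrogates are design choices
of this package: 10 µm is a cell-diameter-scale translocation over a ≥10-min
track, enough to distinguish jitter from genuine displacement. Both
thresholds sit in the configuration and are echoed into every summary file,
so a different operating point is a one-line change, and the tests assert
only the *direction* of the spot→wavy shift between resting and inflamed
cohorts, not exact fractions.

## Preprocessing conventions

* **2D projection.** Tracks are analyzed as 2D projections of the 3D volume;
  axial motion of the villus makes z unreliable, and the projection slightly
  underestimates the speed of cells moving in z. All downstream metrics
  operate on x–y.
* **Drift correction.** Bulk tissue motion (peristalsis, breathing) is
  estimated per frame transition as the componentwise *median*, over all
  cells present at both frames, of their frame-to-frame displacement, and its
  cumulative sum is subtracted from every position. The median keeps the
  estimate robust when a minority of cells is genuinely motile — in effect a
  reference-frame stabilization computed from coordinates alone, without
  image registration. Transitions with no spanning cell receive zero drift.
  The stage is optional (config flag) and the estimated series can be written
  out for audit; on noise-free rigid translations the correction is exact and
  idempotent to numerical precision.
* **Gaps and short tracks.** Tracking software drops cells for a frame or
  two. Gaps of at most `max_gap` missing frames (default 1) are tolerated:
  the track stays whole, but the gap-spanning step is excluded from
  speed-based metrics. No interpolation is performed — interpolating across a
  gap fabricates slow steps and inflates the arrest coefficient. Larger holes
  split the track; segments shorter than `min_track_duration` (default
  10 min) are discarded, because the arrest coefficient of very short tracks
  is high-variance. Split segments keep their parent identity, and the
  metrics table pools them back into one record per cell: speed statistics
  from the pooled uniform steps, displacement statistics from the full
  time-ordered sequence of retained positions (the unobserved hop between
  segments is included in the path length, which keeps straightness ≤ 1 by
  the triangle inequality).

## The two-state simulator

The movies behind the published cohort statistics are not deposited, so the
package ships a generative stand-in whose purpose is narrow: produce cohorts
whose *measured* statistics, through the exact analysis pipeline above, match
the printed values per condition.

Cells switch between an **arrested** and a **patrolling** state according to
a two-state Markov chain at fine time resolution (0.1 min), far below the
60-s frame interval. While arrested, a cell jitters isotropically
(s.d. `sigma_arrest` per fine step); while patrolling, it runs at `v_run`
µm/min with a heading that diffuses (`sigma_turn` radians per fine step).
The stationary arrested-state occupancy is $p_{PA}/(p_{AP}+p_{PA})$, and
initial states are drawn from it. Sub-frame stop-and-go dynamics are the
point: the published "spot"/"wavy" dichotomy and high arrest coefficients
alongside non-trivial mean speeds imply bursts that 60-s sampling does not
resolve, and they let a single model family cover both immotile and
patrolling cohorts.

Acquisition effects are layered on top:

* **Confinement**: reflecting box of half-widths 150 × 50 × 50 µm / 2
  (villus-scale lamina propria); the exact size is cosmetic for the arrested
  regimes and bounds the range of patrolling ones.
* **Tissue drift**: one sinusoidal XY drift (velocity amplitude 1 µm/min,
  period 5 min, random phase and direction) shared by all cells of a
  simulated field — there to exercise the drift-correction stage, not to
  model peristalsis mechanistically.
* **Sampling and localization noise**: positions are kept every 60 s and
  perturbed by isotropic Gaussian localization noise (s.d. 0.3 µm per
  coordinate). For a fully arrested cell this noise floor alone produces a
  measured speed of $\sigma\sqrt{\pi}/\Delta t \approx 0.53$ µm/min — one
  reason "immotile" cohorts never measure exactly zero.

The simulator consumes a fixed number of random draws per step regardless of
parameter values, so paired designs (the same seed with and without drift)
stay aligned draw-for-draw; that is what the drift-correction validation
leans on. A time-course variant switches the regime parameters at an
injection time with state and position continuous at the switch, emulating
antibody-injection-during-imaging experiments.

### Calibration of the regime presets

Each named condition is a point in the 5-dimensional parameter space
(`p_AP`, `p_PA`, `v_run`, `sigma_arrest`, `sigma_turn`). Presets were frozen
by grid search (`analysis/00_calibrate_regimes.R`): each candidate is
simulated as a 500-track cohort at a fixed seed, pushed through the default
pipeline, and scored by the summed relative error of cohort mean speed,
arrest coefficient and straightness against the condition's published
values; calibration fails loudly if no grid point is within 20% on every
statistic. The winning parameters, and the statistics they achieve, are
recorded in `results/calibration_achieved.csv` and hard-coded into
`regime_table()`.

Two honest caveats. First, conditions for which only a direction is printed
("enhanced velocity", "reduced arrest" — flagellin, T-cell-deficient,
crypt/ILF) are *not* calibrated to numbers; their presets are set by hand to
be clearly separated from the arrested regimes, and nothing quantitative is
asserted about them. Second, for the NKp46⁺ steady-state condition the
published pair (mean speed ≈ 3.4 µm/min *and* a >60% majority of arrested
cells) pins down only two of the three scored statistics; the remaining
design targets were chosen so that the winner carries the arrested-cell
majority with a clear margin (~69% at the default cutoff), which forces
patrolling bursts near 34 µm/min — faster than typical interstitial
lymphocyte runs. That is a deliberate compromise of this model family: the
printed cohort statistics are reproduced at the expense of a biologically
high instantaneous run speed.

### What the generator does not emulate

Synthetic cohorts share the acquisition geometry, noise scale and drift of
the real movies, but not their biology: no chemokine fields, no cell–cell
interactions or T-cell competition (blockade conditions are simply distinct
parameter sets), no villus architecture beyond a box, no tracking errors
(identity swaps, missed detections) beyond optional frame dropout in tests.
Passing the cohort-level checks therefore shows that the *analysis* is
faithful and well-calibrated, not that the model is a mechanistic account of
ILC3 motility.

## Statistical comparisons

The statistical unit is the track/cell, as in the figure legends of
intravital studies; per-animal aggregation is out of scope. Pairwise
comparisons use the two-tailed Mann–Whitney U test — exact when the smaller
sample has ≤8 observations and no ties (checked against full enumeration in
the tests), normal approximation with tie and continuity correction
otherwise, with the method reported. Multi-group panels use classic one-way
ANOVA; a zero within-group variance with equal means is reported as
undefined rather than silently producing NaN. No multiple-testing adjustment
is applied by default, matching per-panel reporting of unadjusted tests; a
Holm option exists. Which post-hoc (if any) produced published pairwise
asterisks in multi-group panels is not stated anywhere we could rely on, so
only the omnibus F is implemented.

## Numerical choices and degenerate inputs

* Reflection at the confinement box uses the triangle-wave folding of the
  unconstrained coordinate, exact for piecewise-linear paths.
* Strict `<` at the arrest threshold; ties count as motile.
* The writer emits 15 significant digits, so a write/read round trip is the
  identity to well below 1e-9 µm.
* Frame indices are 1-based in tracking-software exports and converted to a
  0-based physical time origin in minutes internally.
* Degenerate inputs have defined behavior: one-point tracks are flagged (not
  dropped) in the metrics table; zero-length paths give missing straightness;
  empty cohorts, unknown regimes, unknown config keys and frame-grid
  mismatches raise classed errors naming the problem.

## Problem sizes in tests

The validation suite uses 500-track cohorts for the cohort-statistic checks
(the size at which presets were calibrated), 50-cell fields over 50 seeded
replicates for drift-correction recovery, a 3×3 grid of 500-track cohorts
for occupancy recovery, 100 random tracks of up to 50 points for the
MSD-oracle identity, and 1,000 null replicates for the ANOVA size check —
sizes chosen so each property is measured with comfortable Monte-Carlo
margin while the suite stays quick to run.

## Known limitations

* The arrest coefficient uses step counts; with non-uniform sampling (after
  gap exclusion) this is no longer exactly a percentage of *time*. With the
  default uniform 60-s frames the two coincide.
* The drift estimator assumes most cells share the bulk motion at each
  transition; a field where nearly every cell translocates coherently in the
  same direction would be partially "corrected" away.
* Cohort MSD averaging across tracks (rather than pooling intervals) is one
  of two defensible conventions; it is the one matching per-cell figures.
* Simulated run speeds for the NKp46⁺ preset are biologically high (see
  calibration caveats above).
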