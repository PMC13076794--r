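---
title: "Quantifying microglial morphodynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphodynamics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmorph)
```

# Scope and model

Microglia in healthy tissue hold a roughly stationary soma and continuously
remodel a tree of fine processes. The package quantifies that behaviour from
binary per-cell masks in three complementary ways — pixel turnover
(surveillance), outline complexity (ramification), and directed convergence
on a lesion (chemotaxis) — plus static 3D morphometrics of fixed-tissue
stacks, and it implements the aggregation-then-test statistics used to
compare genotypes. This vignette records the definitions, the estimator
choices where several were defensible, the defaults and their units, and the
known limitations. No empirical claims are made here beyond what the test
suite and `scripts/acceptance.R` compute.

## Preprocessing chain

`read_stack()` loads a `T x Z x Y x X` stack with physical calibration
(defaults mirror a common two-photon configuration: 512 x 512 px over a
258 um square field, i.e. 0.504 um/px, 2 um z-steps, 60 s frames; chemotaxis
acquisitions use 30 s frames). The chain is:

1. **Background subtraction** (`subtract_background()`): per frame, subtract
   an intensity percentile (default 10th) and clip at zero. A percentile was
   chosen because the estimator must ignore the sparse bright cell; on a
   background-flat frame the operation is idempotent. The percentile is the
   one tunable; raising it risks eating dim process signal.
2. **Median filtering** (`median_filter()`): exact clipped-window median,
   default radius 1 (3 x 3). Note that a 3 x 3 median erases structures one
   pixel wide; it is therefore *not* applied to the synthetic phantoms, whose
   processes are deliberately single-pixel, and real data with very fine
   processes should be filtered with care.
3. **Drift correction** (`correct_drift()`): every frame is registered to
   frame 1 by maximizing FFT cross-correlation of maximum projections
   (lateral) and z-profiles (axial). Shifts are estimated at integer
   precision — which makes recovery of a commanded integer drift exact and
   testable — and reported in the convention "shift applied to frame t to
   align it to frame 0" (a frame whose content drifted by +d is assigned
   -d). Frames with zero variance inherit the previous shift and are flagged.
4. **Maximum projection** (`max_project()`) and **manual thresholding**
   (`make_cell_masks()`): processes are dimmer than somata, so a single
   automatic threshold misses the periphery; the operator-chosen per-cell
   threshold lives in the annotation file. Foreground is `intensity >=
   threshold` (ties are foreground). Per frame only the 8-connected
   component(s) overlapping the tracked cell are kept: at frame 1 the seeded
   (or largest) component, afterwards the components overlapping the
   previous retained mask. Empty frames are flagged and retained so interval
   series stay aligned. An Otsu fallback (`otsu_threshold()`) exists but is
   never substituted silently.
5. **Z-containment QC** (`qc_z_containment()`): a cell is excluded if at any
   frame any above-threshold voxel lies within a margin (default 1 slice) of
   the top or bottom of the acquired z-range, since partial-volume truncation
   would masquerade as retraction.

Every step appends exactly one provenance record (step name plus
parameters), so a mask sequence documents how it was produced.

All coordinates are 0-based with half-open ROI boxes in `(y, x)` order,
matching the conventions of the sidecar annotation files.

## Surveillance index

For consecutive masks, pixels gained are process extensions (PE) and pixels
lost are retractions (PR); `SI_t = PE_t + PR_t` in pixels per interval, and
`SI_t * s^2 * 60/dt` in um^2/min. Obvious but load-bearing invariants are
tested: swapping frames swaps PE and PR; `|mask_{t+1}| - |mask_t| = PE - PR`;
joint translation of both masks changes nothing.

## Ramification index

`RI = P / (2 sqrt(pi A))` with `A` the pixel-count area. The only subtle
choice is the perimeter estimator `P`:

- Counting exposed pixel edges overestimates a digital disc's perimeter by
  ~27% (every boundary is a staircase), breaking the defining property that
  a disc scores 1.
- The raw 0.5-level marching-squares polygon (edge-midpoint contour) still
  overestimates a disc by ~6%.
- The default therefore measures the marching-squares polygon after one pass
  of circular moving-average vertex smoothing with half-width 2. Measured
  errors: digital disc +0.4% at radius 64 px (+0.2% at radius 16), solid
  square -1.0% against the analytic `2/sqrt(pi)`. Because the polygon is
  extracted from the *binary* mask, single-pixel-wide processes always
  contribute (a Gaussian pre-smoothing of the image would drop them below
  the 0.5 level), and adding a branch to a disc strictly increases RI.

`ramification_index(method = "contour")` (raw polygon) and
`method = "pixel_edge"` remain available for sensitivity analysis. Masks
with fewer than 2 pixels have no meaningful outline; they are flagged and
excluded from per-cell RI means (SI is still computed). For connected
simulated cells RI stays above `1 - 0.05`; the 5% allowance covers polygon
smoothing on small or tortuous masks.

## Chemotaxis

Around the manually placed ablation center, `n_sectors` (default 36) equal
angular sectors partition `[0, 2 pi)`; the angle convention is
counter-clockwise from +x with the image y-axis pointing down
(`theta = atan2(-(y - cy), x - cx)`), sector 0 starting on the +x axis. The
leading edge per sector is the nearest foreground pixel to the center
(pixel-center Euclidean distance, scaled to um). Design choices, recorded
per event:

- Sectors without signal are reported missing and excluded from the
  per-frame summary rather than imputed at the crop radius, which would make
  results depend on crop size.
- The per-frame summary over responding sectors is the mean by default; the
  median is available (`summary_stat`), since either reading is defensible.
- AUC is the trapezoidal integral of the summary distance over time in
  seconds on the native sampling, with no extrapolation beyond acquired
  frames; missing frames are bridged linearly and the bridge count recorded.

A coarse note on interpretation: with more sectors than converging
processes, sectors that contain only somata contribute constant distances
and dilute the slope of the mean curve; the group contrast is unaffected
(both groups are diluted alike), but absolute convergence speed is best read
with `n_sectors` matched to the number of responding processes, as done in
the speed-recovery tests.

## Static 3D morphometrics

`segment_cells()` thresholds at `otsu_scale` x the Otsu level of a 256-bin
histogram (computed after min-max scaling, exhaustive between-class-variance
maximization; the first maximizer is taken on tie plateaus), labels
26-connected components, and drops components below `min_object_voxels`
(defaults 1.0 and 300, in the middle of the 0.5-1.5 / 200-500 ranges used
with such stacks). Optional per-image size-percentile bounds replace fixed
voxel limits for excluding the largest/smallest objects. Border-touching
cells are removed (`exclude_border_cells()`) because their morphology is
truncated.

- **Territory** is the volume of the 3D convex hull of the cell's voxel
  centers in physical coordinates (an own incremental-hull implementation,
  validated against closed forms: unit-edge tetrahedron `1/(6 sqrt 2)` to
  machine precision, digital ball within 5% of `(4/3) pi r^3` for r >= 14 —
  the hull of voxel *centers* is inscribed in the continuum ball, so the
  deficit shrinks like 1/r and radii below ~14 voxels read low). Coplanar
  cells fall back to 2D hull area x z-step, flagged.
- **Skeletons** come from sequential topology-preserving (simple-point)
  thinning with endpoint preservation, on an isotropically resampled grid
  when voxels are anisotropic. Thinning a thick soma leaves short spurious
  spurs, so chains from an endpoint to the nearest junction shorter than
  `prune_um` are pruned iteratively; choose `prune_um` below the shortest
  genuine process (3 um in the test phantoms, whose branches are >= 5 um).
  Branch points are skeleton voxels with >= 3 neighbors (26-connectivity),
  end points have exactly 1; total length is the physical length of the
  minimum spanning tree of the 26-adjacency graph, which avoids
  double-counting the triangles that staircase chains create.
- **Spot density** detects somata as 3 x 3 x 3 local maxima of the smoothed
  soma channel above an intensity floor, with greedy suppression of peaks
  closer than `spot_min_distance_um` to a brighter one; density is count per
  calibrated volume.

These are openly defined metrics named for what they compute; no numeric
equivalence with any external morphometry tool's internal formulas is
implied.

## Statistics

Cell- (or event-) level values are averaged per animal first
(`per_animal_aggregate()`); the group test then sees one value per animal,
and `n_per_group` in every `group_comparison` equals the number of animals.
The two-group test is gated: an F-ratio variance-equality test at alpha 0.05
selects Student's (not rejected) vs Welch's (rejected) two-sided t-test. The
gate's test and alpha are exposed; the F test is the classical choice where
only the gate's existence, not its form, is given. Normality (Shapiro-Wilk)
is reported but not enforced — only parametric tests are in scope. Effect
size is Cohen's d with pooled s.d. (Hedges' correction optional, off by
default). Sign conventions: t carries the sign of (group1 - group2), d and
`direction` the sign of (group2 - group1). The degenerate zero-variance,
equal-means case returns t = 0, p = 1, d = 0, flagged.
`two_way_anova_bonferroni()` is thin plumbing over `aov()` with all pairwise
cell comparisons Bonferroni-adjusted (`min(1, m p)`), for multi-factor
designs (age x genotype x region); a single-level factor degrades to the
one-way layout.

Calibration is tested, not assumed: over 1000 seeded null replicates at
n = 3-4 per group the gated test's type-I error is within 3 binomial s.e. of
0.05, and the textbook case `{1,2,3}` vs `{4,5,6}` reproduces
t = -3.674235, p = 0.021312, d = 3 to 1e-6. Empirical power at d = 2, n = 3
is compared with the noncentral-t prediction; the variance gate perturbs the
procedure slightly relative to a pure Student test, so that check carries a
small (0.02) allowance beyond 3 s.e.

## Synthetic phantoms: what they emulate, and what they do not

The generator (`sim_params()` defaults) reproduces the acquisition regime
the pipeline targets: 258 um / 512 px isotropic frames, 2 um z-steps, 60 s
frames (30 s in chemotaxis mode), a bright soma (painted 1000 a.u.) with
dimmer processes (400 a.u.) over background (100 a.u.) — the intensity
asymmetry that motivates manual thresholds — lateral Gaussian PSF (sigma
1 px), commanded sub-pixel drift, and a standard camera noise model (Poisson
shot noise on the painted intensities, then Gaussian read noise, s.d. 5).
Morphology is a digital soma ball plus 1-voxel-wide branches grown as
persistent lattice random walks (26-connected in 3D, 8-connected in 2D,
which guarantees masks that the 8-connected component tracking and the
contour/skeleton operators handle without special cases). Branches that
would leave the field raise an error naming the offending branch rather than
silently clipping.

Baseline dynamics are phenomenological: each tip moves by the net of
competing Poisson extension and retraction step counts with means
`rate * dt/60 / pixel_size` per frame; with retraction off, the expected PE
per tip and frame is exactly the extension mean, which is the analytic
oracle used in the Monte-Carlo tests (the mean per-interval SI likewise
follows the absolute Skellam difference of the two Poisson counts). The
published literature on these cells reports baseline process speeds of
roughly 1-2.5 um/min, so the defaults (1.5 um/min each way) sit in that
range, but they are chosen for testability, not fitted to any dataset.
Chemotaxis mode arranges converging processes at the centers of an
equal-sector partition around the lesion, each advancing at the commanded
speed, so the true leading-edge distance is `max(0, d0 - v t)` by
construction and the rasterized tips stay within half a pixel of it.

Ground truth records the unrendered, undrifted projected masks, per-interval
PE/PR derived from them, the commanded real-valued and integer-rounded
drift, and the analytic leading-edge series. Two consequences worth noting:
with noise and blur disabled, thresholding the rendering midway between
background and process intensity recovers the true masks bit-exactly (the
basis of the exact-recovery tests); and with them enabled, the phantoms
exercise the realistic failure modes (threshold-dependent thin-process
dropout under blur).

What the phantoms do *not* emulate: multi-cell crowding and contact,
mechanistic cytoskeletal dynamics, soma migration, depth-dependent
attenuation, and z-resolved process motion during a frame. Passing tests
therefore demonstrate that the estimators are correct on data satisfying the
stated acquisition model — not that any particular biological dataset meets
that model.

## Problem sizes

The shipped tests and `scripts/acceptance.R` use 96-192 px crops at the
acquisition pixel size, 4-14 frames per movie, 20 cells per condition in the
rate-recovery sweeps, 8-17 cells or events per synthetic mouse (matching a
3-mice-per-group, 43/51-cell and 27/33-event design), and 1000-replicate
statistical calibrations; these sizes give stable Monte-Carlo comparisons
(3 s.e. criteria) while a full run stays in the minutes range on one core.
The full-frame 512 px default is exercised where the units conversion is
checked.

## Known limitations

- Drift estimation is global per frame (no local deformation) and integer by
  default; sub-pixel content shifted by interpolation is never fully
  reversible, so the simulator also stores the integer-rounded drift for
  exact-recovery tests.
- The RI perimeter is a 2D measure on projections; a 3D surface-based
  ramification score is out of scope.
- The surveillance index does not separate soma displacement from process
  motility; with a stationary soma (as in the phantoms) the distinction is
  moot, but on migrating cells SI conflates the two.
- Chemotaxis masks are analyzed on maximum projections, as is standard for
  this assay; purely axial process motion is invisible to it.
- The spur-pruning length in `skeleton_metrics()` trades soma artifacts
  against short genuine branches and must be set per dataset.
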