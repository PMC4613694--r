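---
title: "Quantifying EMT cell-shape change: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EMT cell-shape change: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmorph)
```

## The problem

Epithelial–mesenchymal transition (EMT) converts compact, cobblestone-shaped
epithelial cells into elongated, motile, spindle-shaped mesenchymal cells;
TGF-β1-treated A549 cultures are the canonical model. The change is usually
reported qualitatively. Quantifying it requires three things: an objective
way to pick cells from an image, shape descriptors computed reproducibly
from each cell's silhouette, and a statistical criterion for which
descriptor separates treated from untreated populations best. `cellmorph`
implements all three, plus a synthetic-scene generator that stands in for
microscopy data.

Crucially, both shape families occur in *both* groups — EMT shifts the
mixture, it does not flip every cell — so group comparison is a
distribution-level question, which is why the pipeline leans on ECDF-based
tests and ROC analysis rather than mean comparisons.

## Cell selection: systematic point grids

A regular lattice of points (period `spacing`, optional offset or seeded
random jitter) is overlaid on each image; any cell containing at least one
lattice point is selected. Selection probability is exactly (number of
lattice-distinct pixel positions) / `spacing`², i.e. proportional to cell
area for cells smaller than one grid box — the classical stereological
point-count argument. The default spacing of 30 px selects roughly half of
the default synthetic cells; the jittered variant makes the scheme formally
unbiased, while the deterministic default mirrors a fixed overlay grid.
Area-proportional selection does mean larger cells are over-represented;
that bias is shared by both groups and is a property of the sampling design,
not of the estimator.

## Geometry: one outline, 29 numbers

All length and area descriptors are computed on a sub-pixel outline polygon
traced through the 0.5 level of the binary mask (marching squares via
`grDevices::contourLines`), not on raw pixel edges: pixel-edge ("city
block") perimeters overestimate a circle's circumference by ~27% and would
wreck every perimeter-based descriptor. Marching squares alone still
overestimates a circle by ~6% because of its half-pixel staircase; a
3-vertex circular moving average suppresses that staircase and brings a
rasterized disc's perimeter to within ~1% and a 100 × 25 rectangle's to
within ~1% of closed form. The window is deliberately small: features wider
than ~2 px — including the boundary roughness the fractal dimension is
meant to see — survive it. Pixel count is kept as the `area` definition
(with a `fill_holes` switch controlling whether interior holes count),
while `area_polygon` is the shoelace area of the traced outline.

Descriptor conventions worth stating:

* **Equivalent ellipse.** Axes are `4 * sqrt(eigenvalue)` of the pixel
  set's second central moment matrix, so a solid ellipse returns its own
  axis lengths. The orientation angle is measured from the image vertical,
  clockwise, in [0, 180°).
* **Centroid diameters** are sampled every 2° (the classical convention).
  For concave shapes the chord is the *total* length of all intersected
  segments along the line; angles whose line misses the polygon entirely
  (possible when the centroid falls outside a strongly bent cell) are
  excluded from the mean and counted in `n_missed`.
* **Feret calipers.** `feret_max` is computed exactly as the hull diameter
  (maximum pairwise hull-vertex distance) and `feret_min` exactly by
  rotating calipers over hull edges; only `feret_mean` uses angular
  sampling, at 1° where the discretization error is negligible. `size_length`
  and `size_width` are the calipers along and across the equivalent-ellipse
  major axis.
* **Fractal dimension** is a box-counting estimate: the outline is scaled so
  its long side spans at least 128 boxes, sampled densely, and occupied-box
  counts at dyadic sizes 2…32 are fitted by least squares in log–log space;
  the slope is clamped to [1, 2]. Box counting is the standard choice when
  no particular fractal model is assumed; absolute values depend on the
  scale range and should only be compared within a pipeline.
* **Degenerate inputs.** Components under `min_area_px` (default 50 px) are
  rejected as segmentation debris; collinear pixel sets floor the minor axis
  at 1 px with a warning; a centroid-to-outline distance below half a pixel
  is floored at 0.5 px. Cells touching the image border are dropped by
  default because a truncated outline falsifies every descriptor.

## Statistics

Per descriptor, the two groups are compared with the two-sample
Kolmogorov–Smirnov test (asymptotic p-values; group sizes here are in the
hundreds to thousands, where exact small-sample corrections are
immaterial). A one-sample KS screen against a normal with the sample's own
moments is provided for distribution checking; descriptor distributions are
generally far from normal, which motivates the nonparametric pipeline.

Discrimination is quantified as ROC AUC via the Mann–Whitney identity
(ties counted half), with the treated group as the positive class and
scores used **as-is**: no automatic direction flipping. This is a
deliberate choice — an orientation-dependent descriptor like the bounding
box ratio `box_xy` then sits honestly near 0.5 instead of being inflated
to ~0.55 by post-hoc flipping. The standard error is Hanley–McNeil's
binormal-free formula. Two AUCs are compared with a two-sided z-test on
the independence approximation; because descriptor pairs measured on the
same cells are almost always *positively* correlated, ignoring the
covariance overstates the variance of the difference, making the test
conservative. A DeLong-style covariance estimate would sharpen it and is a
known limitation, not an error. No multiple-testing correction is applied
across the descriptor family or the pairwise matrix; the report says so in
its footer, and the ranking — not any single p-value — is the primary
output.

## The synthetic-scene generator

The generator emulates the statistical structure the analysis assumes, not
the optics of microscopy. Each scene is a label image (512 × 512 px) of
non-overlapping, 1-px-separated silhouettes:

* **Epithelial** cells: superellipses (exponent 2–3) with smooth low-order
  radial lobes, aspect ratio lognormal with median 1.2 and sdlog 0.35 —
  epithelial sheets do contain moderately elongated cells, and that tail is
  what keeps elongation descriptors honest.
* **Mesenchymal** cells: tapered spindles (half-width `∝ sin^(2p)` with
  taper exponent 0.5–0.9, giving pointed ends) whose centreline is bent
  into a circular arc with total turn uniform in [1.2, 3.0] rad.
  Migratory mesenchymal cells are rarely straight rods; bending is the
  generator's expression of that, and it has a useful analytic property:
  it lowers the moment-based aspect ratio while leaving the
  perimeter–area relation (roundness) and the centroid radius extremes
  (radius ratio) nearly unchanged. That asymmetry, not any hand-set AUC,
  is what makes roundness and radius ratio the most robust descriptors in
  recovery experiments — mirroring their standing in real EMT morphometry.
* Both families share one size distribution (equivalent radius lognormal,
  median 12 px, sdlog 0.25), are uniformly randomly oriented (making
  `box_xy` uninformative by construction) and get ±0.4 px vertex jitter.
* Groups differ only in mixture fraction: 85% epithelial untreated vs 30%
  treated. Under perfect class separation this caps every descriptor's
  group AUC near 0.78; observed top AUCs of ~0.74–0.75 sit close to that
  ceiling.

Default problem sizes are 30 images per group and 40 cells per image
(~1 200 grid-selected cells per run), chosen as a realistic desk-scale
experiment of this design; tests that repeat the recovery over 10 seeds use
these same defaults.

What the generator does **not** emulate: cell–cell adhesion and touching
cells, intensity/texture, segmentation errors from real outlining, spatial
clustering, and any absolute size calibration. Passing recovery tests
therefore demonstrates that the pipeline measures and ranks what it claims
on clean segmentations — not that any particular AUC value will be observed
on real micrographs.

## Numerical and design choices, in brief

* Marching squares at level 0.5 + 3-point smoothing (closed-form fidelity
  on discs/rectangles/ellipses within 1–3%).
* Components are 8-connected (background 4-connected, the dual), labels
  ordered by first pixel in row-major scan order; labelling is
  deterministic.
* Chord/caliper tie-breaks: exact vertex hits on a chord line are nudged by
  1e-12; equal AUCs sort stably by descriptor name; equal montage keys sort
  by cell id.
* Two-hue image loading assigns every pixel to the nearer declared hue if
  within RGB distance 30 (absorbing JPEG artefacts), and errors with a hue
  histogram otherwise.
* Seeds: every stochastic component (scene set, grid jitter) takes an
  explicit seed and restores the caller's RNG state; a run is reproducible
  from its echoed config alone.

## Known limitations

* The AUC comparison ignores between-descriptor correlation (conservative).
* Fractal-dimension absolute values are scale-range dependent.
* Border-cell exclusion means per-image cell counts depend on framing; the
  measured-cell totals are reported, not fixed.
* The generator's distribution parameters are package defaults, not fitted
  to any measured cell population; only the qualitative behaviour
  (descriptor ordering, null calibration) is intended to transfer.
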