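# cellmorph

Quantitative cell-shape morphometry for epithelial–mesenchymal transition
(EMT) studies.

When epithelial cells (e.g. A549 lung-adenocarcinoma cultures) undergo EMT —
for instance after TGF-β1 stimulation — their silhouettes shift from compact
"cobblestone" shapes toward elongated, often curved "spindle" shapes. Most
studies describe this shift qualitatively. `cellmorph` implements the
quantitative alternative for anyone working from segmented cell images: it
selects cells objectively with a systematic point grid, measures 28 classical
shape descriptors per cell (plus plain perimeter), and identifies which
descriptors discriminate a treated from an untreated population best.

## What it computes

For each segmented cell (a binary mask), the package traces a sub-pixel
outline and derives, among others:

- **roundness** = P² / (4πA), the inverse isoperimetric quotient: 1 for a
  circle, growing with elongation and boundary irregularity;
- **radius ratio** = max / min distance from the centroid to the outline;
- **aspect** = major / minor axis of the moment-equivalent ellipse (the
  ellipse sharing the region's first and second moments);
- centroid diameters at 2° steps, Feret (caliper) diameters, bounding-box
  ratios, convex and equivalent-ellipse perimeters, and a box-counting
  fractal dimension of the outline.

The statistical stage compares each descriptor's distribution between
groups with a two-sample Kolmogorov–Smirnov test, ranks descriptors by ROC
AUC (Mann–Whitney identity, treated group = positive class, scores used
as-is) with Hanley–McNeil standard errors, and compares AUCs pairwise with
a two-sided z-test, z = (A₁ − A₂) / √(SE₁² + SE₂²).

Because suitable public image sets are rare, a seeded synthetic-scene
generator produces label images of two groups — an epithelial-dominated and
a mesenchymal-dominated mixture of both shape families — so the entire
pipeline can be exercised, calibrated and regression-tested end to end.

## Worked example

```r
library(cellmorph)

# simulate 30 + 30 labelled images, grid-select cells, measure, rank
res <- run_pipeline(run_config(seed = 1))
print(res$report)
```

```
Descriptor ranking by ROC AUC (positive n = 581, negative n = 650)
rank descriptor                AUC       SE       KS p
   1 radius_ratio           0.7466   0.0141          0
   2 roundness              0.7435   0.0141          0
   3 aspect                 0.7412   0.0142          0
   4 axis_major             0.6686   0.0154          0
   5 radius_max             0.6643   0.0155          0
...
```

581 treated and 650 untreated cells were hit by the sampling grid and
measured. Radius ratio and roundness top the ranking (their AUCs are
statistically indistinguishable, `res$report$pairwise_p` gives p ≈ 0.88),
aspect follows, and size-type descriptors rank lower because cell size
varies independently of shape class. Orientation-dependent descriptors such
as `box_xy` sit near AUC 0.5 — cells are randomly oriented, so the
width/height ratio of the bounding box carries no information.

Single-cell measurements are available directly:

```r
m <- matrix(0, 40, 40); m[10:30, 14:26] <- 1   # a 21 x 13 rectangle
f <- shape_features(cell_shape(m))
round(f[c("roundness", "aspect", "radius_ratio", "area")], 3)
#>   roundness aspect radius_ratio area
#> 1     1.255  1.618        1.826  273
```

A thin command-line wrapper is provided at `inst/scripts/cellmorph.R`.

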