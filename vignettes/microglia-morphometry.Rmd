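---
title: "Quantifying microglial morphology, behavior and expression after brain injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphology, behavior and expression after brain injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmorph)
```

## The problem

After a focal brain injury, microglia shift from a *ramified* morphology
(small soma, long branched processes surveying the tissue) toward an
*amoeboid* one (enlarged soma, retracted processes, high circularity),
with *rod-shaped* bipolar cells appearing as a third, putatively
neuroprotective state near lesions. mgmorph quantifies that shift from
microscopy-derived cell masks, and rounds out the injury phenotype with
open-field locomotion and gait kinematics from pose-estimation tables,
perilesional density/coverage measurements, and relative qPCR expression.
Because the raw microscopy and video of such studies are rarely deposited,
the package also carries a first-class synthetic-data module that
generates every input with known ground truth, so each stage of the
pipeline is testable end to end.

## Image preparation

Z-stacks (`image_stack`) are flattened by maximum intensity projection,
background-corrected by subtracting a wide Gaussian estimate of the
illumination field (default sigma 25 µm, configurable; an optional
difference-of-Gaussians band-pass stage provides contour enhancement),
and binarized with Otsu's threshold. `isolate_cells()` then labels
connected components and keeps up to `n_target` nonoverlapping single
cells: components touching the border are discarded, areas outside
50–5,000 µm² are discarded (debris / merged clusters at typical
magnification), and any pair of components whose bounding boxes overlap
within a 2 px margin is discarded as "overlapping" — the source protocol
names the rule but not its definition, so disjoint margin-expanded
bounding boxes is our reading. When more than `n_target` survivors exist,
selection is by descending area with a deterministic (row, col)
tie-break.

## The sixteen morphometric parameters

`morphometric_profile()` computes, per cell mask:

* **Fractal dimension** — box-counting slope of log N(s) vs log(1/s)
  over a geometric ladder of box sizes (powers of 2 from 2 px to
  min(h,w)/4, at least 4 points; masks are padded to 64 px as needed).
  Measured on the outline set by default (`fd_mode = "filled"` is the
  sanity-check alternative). Box-count discretization can push very
  small smooth outlines slightly below 1; values are not clamped.
* **Lacunarity** — gliding-box statistic Λ(r) = var(m)/mean(m)² + 1,
  averaged over box sizes. Inside the profile it is measured over the
  cell's *tight bounding box* (minimum 2 ladder points): measured there
  it indexes the gap structure of the arbor itself — near 1 for compact
  blobs, well above 1 for sparse ramified or rod-shaped arbors. On a
  shared padded canvas the statistic is instead dominated by how much
  empty canvas surrounds the cell, which inverts the expected
  ramified/amoeboid ordering; this was the deciding observation.
* **Areas, perimeters, circularities, density, roughness** — cell area
  is the foreground pixel count; the cell perimeter is the length of the
  marching-squares outline polygon lightly smoothed with a 3-vertex
  circular moving average (window 3 keeps a rasterized disc's
  circularity within 2% of 1 while barely moving polygonal shapes —
  larger windows start rounding square corners past tolerance). The
  convex hull of that contour gives hull area (Shoelace) and perimeter;
  circularity is 4πA/P², density = cell/hull area, roughness =
  cell/hull perimeter.
* **Process lengths and straightness** — Zhang–Suen thinning, then a
  branch decomposition of the skeleton graph (igraph; edge weights 1 and
  √2). Diagonal edges whose corner is bridged by a 4-connected leg are
  dropped, so right-angle bends stay simple paths instead of spawning
  spurious triangle junctions. Terminal spurs shorter than `prune_um`
  (default 2 µm) are pruned *at pixel level* and the decomposition is
  recomputed, so branches separated by a pruned spur merge back into one
  path. Straightness is the unweighted per-branch mean of Euclidean
  end-to-end distance over path length; a branchless skeleton (a blob
  collapsing to a point) scores 1 — a degenerate path has no
  tortuosity, and NA would break the min–max scaling downstream.
* **Sholl maximum** — concentric circles every `sholl_step_um`
  (default 2 µm) around the soma centroid; intersections are counted as
  8-connected runs of skeleton pixels in a one-pixel band around each
  circle, and the profile maximum is reported.
* **Cell body area** — the soma is the largest 4-connected component
  surviving a morphological opening (disc, default radius 2 µm); its
  outer contour polygon is measured with the Shoelace theorem.
  4-connectivity matters: a 4-connected region has a single outer
  contour loop, so the polygon is well defined in any orientation.

Doubling `pixel_size_um` (with the µm-valued tuning parameters scaled
along) exactly doubles lengths, quadruples areas and leaves
dimensionless features untouched. Under 90° rotation all features are
stable to within 5% except max/mean branch length (thinning resolves
junctions orientation-dependently; tested at a wider band) and the Sholl
maximum (±1 count).

## Classification and the amoeboid ratio

Each feature carries a multimodality index (MMI), realized as the
Sarle-type bimodality coefficient b = (g₁² + 1)/(g₂ + 3(n−1)²/((n−2)(n−3)))
— the usage of the morphometry literature the protocol cites; the source
names the index but not a formula. The shipped reference table
(`mmi_reference()`) carries the published per-feature MMI values and
direction labels (5 amoeboid-direction, 11 ramified-direction) and is the
default for reproduction; `mmi_from_data()` re-derives weights for new
datasets. Features are min–max scaled across the analyzed population,
and each cell gets an amoeboid and a ramified index as the MMI-weighted
*mean* of the scaled features of that direction. A weighted mean rather
than the raw sum: sums over 5 vs 11 features are incommensurable, and
the comparison rule ("assign the type with the larger value") only makes
sense on a common scale; `method = "sum"` restores raw sums. Ties go to
ramified — conservative with respect to claims that a treatment reduces
amoeboid counts. The per-sample percentage of amoeboid-classified cells
is the amoeboid ratio.

## Clustering and PCA

Features with MMI ≥ 0.5 (five of sixteen under the reference table)
enter Ward hierarchical clustering (`ward.D2` on Euclidean distances,
z-scored columns by default; min–max is a config alternative). The tree
is cut at every k in 2–8 (the source reports four clusters but not the
scanned range) and the cut maximizing the mean silhouette width wins.
PCA is centered, with a reproducible sign convention
(largest-magnitude loading positive) and a warning when PC1+PC2 explain
less than 70% of the variance — the adequacy bar used for 2D morphology
maps; `pc_centroids()` computes per-group centroids in PC space (the
space the published maps annotate, though they do not say so).

## Behavior

Pose tables use the DeepLabCut CSV dialect (three header rows;
`read_dlc_csv()`/`write_dlc_csv()`). Keypoints below confidence 0.9 are
dropped with linear interpolation across gaps of at most 5 frames;
positions are median-smoothed over 3 frames to suppress tracking spikes
(raw variants exposed via arguments). Locomotion metrics (total
distance, average and maximum speed) come from the hip keypoint;
occupancy maps conserve the valid-frame count exactly. Straight-walk
windows are 1 s, non-overlapping, with mean speed ≥ 3 cm/s and net
heading change ≤ 20°/s ("periods of straight walking" is all the source
states; these are our operational criteria), ranked by net-displacement
straightness. Within each window the unsigned nose–hip–tail-base
interior angle is fit with A·cos(2πft + φ) + c by bounded
nonlinear least squares (f in 1–8 Hz, initialized from the dominant
spectral peak's magnitude *and phase*, with fallback phase starts);
|A| averaged per mouse indexes locomotor coordination. Grip strength is
mean trial force over body weight in grams.

## Quantification and expression

`roi_cell_density()` counts centroids in a 500 × 500 µm ROI (0.25 mm²)
with half-open bounds so tiled ROIs never double-count;
`positive_area_fraction()` reports the suprathreshold percentage of the
ROI under a fixed (recorded) or Otsu threshold — the original manual
thresholds are unrecoverable, so the fixed-intensity path emulates them
explicitly. `relative_expression()` implements the comparative ΔCq
method: replicate Cq values are averaged arithmetically (source silent),
ΔCq is taken against the reference gene per sample, expression is
2^(−ΔCq) with efficiency fixed at 2, and fold change divides by the
control-group mean (equivalent to ΔΔCq on group means; whether the
source used ΔCq or ΔΔCq for its "fold change relative to control" is
ambiguous, so the implemented convention is stated here and in the
function documentation).

## The synthetic world

The generators state a fixed world; their defaults were chosen once and
are not tuned against tests:

* **Ramified cells** — soma radius 6 µm; 5 primary processes grown as
  random walks (step 2 µm, 16 steps, direction jitter 0.22 rad/step,
  branching probability 0.08/step, depth ≤ 3), rasterized at 1 px and
  dilated to 2–3 px so thinning can recover the generative tree.
* **Amoeboid cells** — soma radius 9 µm (activated cells have enlarged
  bodies), elongation 1.2, low-order boundary wobble, no processes.
* **Rod cells** — soma radius 6 µm, elongation 4, two near-straight
  polar processes.
* Pixel size 0.8 µm; signal 200 on an 8-bit scale split over 3 z-planes
  (max projection recovers it), above a low-order polynomial background
  (amplitude 25) plus Gaussian noise (sd 5). Walks: 40 cm arena, 30 fps,
  5 cm/s, gait amplitude 12° at 2.5 Hz (a plausible mouse stride rate),
  Beta-distributed keypoint confidence near 1 with 1% dropouts. Cq
  tables: reference gene at Cq 20, targets in the mid-20s, replicate sd
  0.3 cycles.

What a green test establishes, and what it does not: the generators
produce clean single cells with known class, so classification-recovery
results certify the *pipeline*, not performance on real tissue — real
images add overlapping cells, uneven staining, out-of-focus light and
ambiguous intermediate morphologies that this world deliberately omits
(as do photorealistic optics, 3D process structure, and any quantitative
"jellyfish-like" class, for which no published description exists — the
generator offers only the three classes above, and on such data the
silhouette correctly selects three clusters rather than the four
reported on real injured cortex). One quantitative caveat measured
during development: the generative polyline length of a wiggly, dilated
process exceeds its thinned skeleton length, so skeleton totals track
generator ground truth within about −40%/+20% plus a soma allowance,
while on straight-segment trees agreement is within 10%.

`run_synthetic_study()` assembles the full stated world (2 groups × 4
mice × 20 cells by default; control mice amoeboid-dominated at
15/70/15% ramified/amoeboid/rod, treated mice shifted to 50/20/30%;
gait amplitude 6° vs 12°; an iNOS-like gene shifted +1 cycle in the
treated group) and writes deterministic CSVs — the same seed is
byte-identical across runs.

## Numerical choices and degenerate inputs

* Otsu operates on a 256-bin histogram; constant images are an error.
* Contours come from `contourLines` (marching squares) on the
  zero-padded mask; the largest loop is measured.
* Gliding-box lacunarity uses population variance and an integral image;
  boxes glide at stride 1 fully inside the frame.
* Seeds: every generator takes one explicit seed, runs under a local RNG
  state and restores the caller's; derived seeds stay below 2³¹.
* Empty skeletons, constant features, samples lacking the reference
  gene, ROIs leaving the image, and unplaceable sections all raise
  warnings or errors rather than silently truncating.

## Interface note

This is an analysis package: the exported functions,
`run_synthetic_study()`, and `scripts/acceptance.R` are the interface.
No shell CLI is shipped; every operation named in the protocol is an
exported, documented function.
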