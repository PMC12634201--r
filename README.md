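# mgmorph

Quantitative analysis of glial and behavioral responses to focal brain
injury in mice. After injury, microglia shift from a **ramified**
morphology (small soma, long branched processes) toward an **amoeboid**
one (enlarged soma, retracted processes), with **rod-shaped** bipolar
cells as a third state near lesions. mgmorph turns single-cell masks into
sixteen morphometric parameters, classifies cells with a
bimodality-weighted index, and complements the histology with open-field
kinematics and relative qPCR expression. A seeded synthetic-data module
generates every input with ground truth, so the whole stack is testable
without the (undeposited) raw microscopy and video.

## What it computes

* **Image preparation** — maximum projection of z-stacks, Gaussian
  background subtraction (optional band-pass contour enhancement), Otsu
  binarization, isolation of nonoverlapping single cells
  (`max_project`, `correct_background`, `binarize_otsu`, `isolate_cells`).
* **Morphometry** (`morphometric_profile`) — box-counting fractal
  dimension, gliding-box lacunarity Λ = var(m)/mean(m)² + 1, cell and
  convex-hull area/perimeter, circularity 4πA/P², density, roughness,
  skeleton process lengths with straightness (Euclidean / path length),
  Sholl maximum intersection count, and Shoelace cell-body area.
* **Classification** (`classify_profiles`, `amoeboid_ratio`) — features
  weighted by the multimodality index
  b = (g₁² + 1) / (g₂ + 3(n−1)²/((n−2)(n−3))), min–max scaled, and
  combined into amoeboid/ramified indices; a cell takes the larger
  index's label, and the per-sample percentage of amoeboid cells is the
  amoeboid ratio.
* **Clustering / PCA** (`select_features`, `cluster_cells`, `pca_embed`)
  — Ward clustering on MMI ≥ 0.5 features with silhouette-selected k,
  centered PCA with explained-variance reporting.
* **Quantification** (`roi_cell_density`, `positive_area_fraction`) —
  cells/mm² and immunopositive-area % in a 500 × 500 µm perilesional ROI.
* **Behavior** (`locomotion_metrics`, `occupancy_map`,
  `straight_walk_segments`, `gait_amplitude`, `grip_index`) — distance
  and speeds from pose-estimation keypoint tables (DeepLabCut CSV
  dialect), occupancy heatmaps, cosine-fit gait amplitude
  A·cos(2πft + φ) + c on the nose–hip–tail-base angle, grip force per
  gram body weight.
* **Expression** (`relative_expression`) — comparative ΔCq:
  2^(−ΔCq) against a reference gene, fold change vs the control mean.
* **Synthetic data** (`make_cell_image`, `make_section`,
  `make_trajectory`, `make_cq_table`, `run_synthetic_study`) — seeded,
  bit-reproducible generators for all of the above.

## Worked example

```r
library(mgmorph)

# one synthetic ramified cell, through preprocessing and morphometry
cell <- make_cell_image(cell_shape_spec("ramified", seed = 3))
img  <- max_project(cell$stack)
mask <- binarize_otsu(correct_background(img, pixel_size_um = 0.8))$mask
prof <- morphometric_profile(cell$mask)
round(unlist(prof[c("fractal_dimension", "cell_circularity",
                    "total_process_length_um", "sholl_max_counts")]), 3)
#>       fractal_dimension        cell_circularity total_process_length_um
#>                   1.318                   0.056                 205.586
#>        sholl_max_counts
#>                   8.000
```

A fractal dimension of 1.32 and circularity of 0.06 with 206 µm of
process and a Sholl maximum of 8 is a textbook ramified profile; an
amoeboid cell from the same generator scores circularity ≈ 0.95 with
almost no measurable process. Running the full seeded study,

```r
res <- run_synthetic_study(tempdir(), seed = 1)
res$ratios[, c("sample", "amoeboid_ratio")]
#>      sample amoeboid_ratio
#> 1 control_1             85
#> ...
#> 5 treated_1             50
```

control mice (amoeboid-dominated mix) score an amoeboid ratio of 85%
against 50% in treated mice — the direction of effect the pipeline is
built to measure — alongside gait amplitudes of ≈6° vs ≈12° and an
iNOS-like fold change of ≈0.5 in the treated group.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the complete synthetic study at the given seed and runs
every pipeline stage on it (morphometry, classification, clustering,
PCA, behavior, quantification, expression), then writes the JSON report
to `--out`.
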