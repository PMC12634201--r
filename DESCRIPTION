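Package: mgmorph
Title: Microglial Morphometry, Behavior and Expression Analysis for
    Brain-Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis stack for mouse brain-injury studies:
    single-microglia morphometric profiling (box-counting fractal dimension,
    gliding-box lacunarity, convex-hull shape metrics, skeleton process
    lengths, Sholl analysis, cell body area), bimodality-weighted
    amoeboid/ramified classification and the per-sample amoeboid ratio,
    Ward hierarchical clustering with silhouette-based cluster-number
    selection and PCA embedding, perilesional glial density and coverage
    quantification, open-field locomotion and cosine-fit gait kinematics
    from pose-estimation keypoint tables, grip-strength normalization, and
    relative qPCR expression via the comparative delta-Cq method.  A seeded
    synthetic-data module generates every input the pipeline consumes
    (cell images of three morphology classes, multi-cell sections,
    locomotion trajectories, Cq tables) with ground-truth labels so each
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    grDevices,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
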