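# Synthetic generators: determinism, ground-truth guarantees, recovery by
# the preprocessing pipeline.

test_that("generators are pure functions of spec and seed", {
  s <- cell_shape_spec("ramified", seed = 42)
  a <- make_cell_image(s); b <- make_cell_image(s)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$mask$pixels, b$mask$pixels)
  s2 <- cell_shape_spec("ramified", seed = 43)
  expect_false(identical(make_cell_image(s2)$mask$pixels, a$mask$pixels))

  w <- walk_spec(duration_s = 5, seed = 7)
  expect_identical(as.data.frame(make_trajectory(w)),
                   as.data.frame(make_trajectory(w)))

  q <- cq_spec(seed = 11)
  expect_identical(make_cq_table(q), make_cq_table(q))

  # no global RNG leakage
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(make_cell_image(s)); after <- runif(1)
  expect_identical(before, after)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(cell_shape_spec("ramified", branch_prob = 1.5), "branch_prob")
  expect_error(cell_shape_spec("rod", elongation = 0.5), "elongation")
  expect_error(cell_shape_spec("amoeboid", noise_sd = -1), "noise_sd")
  expect_error(walk_spec(gait_freq_hz = 20, fps = 30), "fps/2")
  expect_error(cq_spec(n_per_group = 1), "n_per_group")
  expect_error(cq_spec(genes = c("a", "b"), reference_gene = "GAPDH"),
               "reference")
})

test_that("ramified masks expose at least n_primary skeleton endpoints", {
  for (seed in c(1, 5, 12)) {
    spec <- cell_shape_spec("ramified", seed = seed)
    cell <- make_cell_image(spec)
    skel <- mgmorph:::skeletonize(cell$mask$pixels)
    expect_gte(mgmorph:::skeleton_endpoints(skel),
               spec$n_primary_processes)
  }
})

test_that("amoeboid masks with elongation 1 are near-circular", {
  cell <- make_cell_image(cell_shape_spec("amoeboid", elongation = 1,
                                          noise_sd = 0, seed = 2))
  met <- hull_and_shape_metrics(cell$mask)
  expect_gte(met$cell_circularity, 0.8)
})

test_that("cell images are recovered by the preprocessing pipeline", {
  for (cls in c("ramified", "amoeboid", "rod")) {
    cell <- make_cell_image(cell_shape_spec(cls, noise_sd = 0, seed = 3))
    img <- max_project(cell$stack)
    corr <- correct_background(img, pixel_size_um = 0.8)
    rec <- binarize_otsu(corr)$mask
    jac <- sum(rec & cell$mask$pixels) / sum(rec | cell$mask$pixels)
    expect_gte(jac, 0.8)
  }
  expect_error(
    make_cell_image(cell_shape_spec("ramified", seed = 1), canvas_px = 16),
    "too small")
})

test_that("sections place the requested class mix without overlap", {
  sec <- make_section(30, class_mix = c(1, 1, 1), field_um = 700,
                      pixel_size_um = 1, seed = 5)
  expect_equal(nrow(sec$centroids), 30)
  expect_equal(as.vector(table(sec$centroids$morph_class)[
    c("ramified", "amoeboid", "rod")]), c(10, 10, 10))
  expect_true(all(sec$centroids$row >= 1 &
                    sec$centroids$row <= nrow(sec$mask)))

  all_ram <- make_section(8, class_mix = c(1, 0, 0), field_um = 500,
                          seed = 6)
  expect_true(all(all_ram$centroids$morph_class == "ramified"))

  s1 <- make_section(12, field_um = 500, seed = 1)
  s2 <- make_section(12, field_um = 500, seed = 2)
  expect_false(identical(s1$centroids$row, s2$centroids$row))
  expect_equal(nrow(s1$centroids), nrow(s2$centroids))

  expect_error(make_section(500, field_um = 300, seed = 1, max_tries = 5),
               "overlap")
})

test_that("trajectories respect construction guarantees", {
  # straight walk: path length equals speed x duration
  ws <- walk_spec(duration_s = 10, speed_cm_s = 5, turn_sd_deg = 0,
                  dropout_rate = 0, seed = 1)
  traj <- make_trajectory(ws)
  cmpx <- attr(traj, "cm_per_px")
  d <- sum(sqrt(diff(traj$hip_x)^2 + diff(traj$hip_y)^2)) * cmpx
  expect_lt(abs(d - 50) / 50, 0.01)

  # zero amplitude: constant segment angle
  ws0 <- walk_spec(duration_s = 5, gait_amplitude_deg = 0, turn_sd_deg = 0,
                   dropout_rate = 0, seed = 2)
  ang <- segment_angles(make_trajectory(ws0))
  expect_lt(max(ang) - min(ang), 1e-6)

  # all keypoints inside the arena
  ws3 <- walk_spec(duration_s = 30, turn_sd_deg = 45, seed = 3)
  t3 <- make_trajectory(ws3)
  for (bp in c("nose", "hip", "tail_base")) {
    expect_true(all(t3[[paste0(bp, "_x")]] * cmpx >= 0 &
                      t3[[paste0(bp, "_x")]] * cmpx <= 40))
    expect_true(all(t3[[paste0(bp, "_y")]] * cmpx >= 0 &
                      t3[[paste0(bp, "_y")]] * cmpx <= 40))
  }
})

test_that("cq tables carry the injected group effect exactly at sd 0", {
  spec <- cq_spec(n_per_group = 3, genes = c("GAPDH", "geneX"),
                  group_effect_log2 = c(geneX = -1), cq_sd = 0, seed = 1)
  tab <- make_cq_table(spec)
  res <- relative_expression(tab)
  treated <- res$fold_change[res$group == "treated" & res$gene == "geneX"]
  expect_equal(treated, rep(2, 3))

  # zero effect, zero sd: all folds exactly 1
  spec0 <- cq_spec(n_per_group = 2, genes = c("GAPDH", "g1", "g2"),
                   group_effect_log2 = numeric(0), cq_sd = 0, seed = 2)
  res0 <- relative_expression(make_cq_table(spec0))
  expect_true(all(res0$fold_change == 1))
})

test_that("synthetic class structure matches morphometric expectations", {
  # batch means: ramified cells have longer skeletons and lower
  # circularity than amoeboid cells at matched soma size
  n <- 50
  tot_r <- circ_r <- tot_a <- circ_a <- numeric(n)
  for (i in seq_len(n)) {
    r <- make_cell_image(cell_shape_spec("ramified", soma_radius_um = 6,
                                         seed = i))
    a <- make_cell_image(cell_shape_spec("amoeboid", soma_radius_um = 6,
                                         seed = i + 500))
    sr <- skeleton_metrics(r$mask)
    sa <- suppressWarnings(skeleton_metrics(a$mask))
    tot_r[i] <- sr$total_process_length_um
    tot_a[i] <- sa$total_process_length_um
    circ_r[i] <- hull_and_shape_metrics(r$mask)$cell_circularity
    circ_a[i] <- hull_and_shape_metrics(a$mask)$cell_circularity
  }
  expect_gt(mean(tot_r), mean(tot_a))
  expect_lt(mean(circ_r), mean(circ_a))
})

test_that("PGM image round-trip preserves intensities", {
  set.seed(4)
  img <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path)
  expect_identical(read_pgm(path), img + 0)
  unlink(path)
})
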