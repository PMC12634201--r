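# Morphometric parameters: geometry, fractal/lacunarity, skeleton, Sholl.

test_that("circularity is ~1 for discs and ~pi/4 for squares", {
  disc <- hull_and_shape_metrics(disc_mask(50), pixel_size_um = 1)
  expect_lt(abs(disc$cell_circularity - 1), 0.05)
  expect_gte(disc$density, 0.98)
  expect_lte(disc$roughness, 1.05)

  sq <- hull_and_shape_metrics(square_mask(50), pixel_size_um = 1)
  expect_lt(abs(sq$cell_circularity - pi / 4), 0.03)
})

test_that("hull area of a star polygon matches the Shoelace of its hull", {
  # 4-pointed star with known vertices; its hull is the 8-gon of outer and
  # inner-diagonal points -- here simply check the hull of the rasterized
  # star against the Shoelace area of the hand-listed hull vertices
  n <- 81; c0 <- 41
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- abs(i - c0); dy <- abs(j - c0)
    m[i, j] <- (dx / 30 + dy / 8 <= 1) || (dx / 8 + dy / 30 <= 1)
  }
  got <- hull_and_shape_metrics(m, pixel_size_um = 1)
  # the convex hull of the two crossed diamonds is the outer diamond
  # through the four long tips: Shoelace of (30,0),(0,30),(-30,0),(0,-30)
  tips <- rbind(c(30, 0), c(0, 30), c(-30, 0), c(0, -30))
  oracle <- polygon_area(tips[, 1], tips[, 2])
  expect_identical(oracle, 1800)
  expect_equal(got$convex_hull_area_um2, oracle, tolerance = 0.05)
  expect_error(hull_and_shape_metrics(matrix(c(TRUE, rep(FALSE, 24)), 5, 5)),
               "small")
})

test_that("Shoelace polygon area is exact on printed toy polygons", {
  expect_identical(polygon_area(c(0, 4, 4, 0), c(0, 0, 3, 3)), 12)
  expect_identical(polygon_area(c(0, 4, 0), c(0, 0, 3)), 6)
  # winding order and starting vertex do not matter
  expect_identical(polygon_area(c(4, 0, 0, 4), c(0, 0, 3, 3)), 12)
})

test_that("fractal dimension recovers line, plane and Sierpinski carpet", {
  line <- matrix(FALSE, 512, 512); line[256, ] <- TRUE
  expect_lt(abs(fractal_dimension(line, mode = "filled") - 1), 0.1)

  filled <- matrix(TRUE, 256, 256)
  expect_lt(abs(fractal_dimension(filled, mode = "filled") - 2), 0.1)

  carpet <- carpet_mask(4, 3)
  expect_lt(abs(fractal_dimension(carpet, mode = "filled") -
                  log(8) / log(3)), 0.08)
  expect_error(fractal_dimension(matrix(TRUE, 16, 16)), "small")
})

test_that("lacunarity is exactly 1 on filled images and matches brute force", {
  filled <- matrix(TRUE, 64, 64)
  expect_equal(lacunarity(filled), 1, tolerance = 1e-12)
  expect_true(all(lacunarity_profile(filled) == 1))

  # single pixel in a large field: extreme heterogeneity
  lone <- matrix(FALSE, 64, 64); lone[32, 32] <- TRUE
  expect_gt(lacunarity(lone), 50)

  set.seed(3)
  scatter <- matrix(runif(64 * 64) < 0.5, 64, 64)
  sizes <- c(2, 4, 8, 16)
  expect_equal(lacunarity_profile(scatter, sizes),
               lacunarity_brute(scatter, sizes), tolerance = 1e-9)

  checker <- outer(1:64, 1:64, function(i, j) (i + j) %% 2 == 0)
  expect_lt(lacunarity(checker), lacunarity(scatter))
})

test_that("skeleton metrics recover bar and L-shape straightness", {
  bar <- skeleton_metrics(bar_mask(80), pixel_size_um = 1, prune_um = 3)
  expect_lt(abs(bar$straightness - 1), 0.02)
  expect_equal(bar$n_branches, 1L)
  expect_lt(abs(bar$total_process_length_um - 80), 5)

  a <- 60; b <- 60
  l <- skeleton_metrics(l_mask(a, b), pixel_size_um = 1, prune_um = 3)
  expect_lt(abs(l$straightness - sqrt(a^2 + b^2) / (a + b)), 0.05)

  # synthetic tree with known generative branch lengths: a T of three arms
  tr <- matrix(FALSE, 120, 120)
  tr[20:100, 59:61] <- TRUE    # vertical bar, length ~80
  tr[59:61, 20:100] <- TRUE    # horizontal bar, length ~80
  cross <- skeleton_metrics(tr, pixel_size_um = 1, prune_um = 3)
  expect_lt(abs(cross$total_process_length_um - 160), 16)
  expect_equal(cross$n_branches, 4L)
})

test_that("skeleton total length tracks known generative branch lengths", {
  # tree of straight segments with exact generative lengths, drawn at
  # 1 px and dilated to process width like the cell generator
  seg <- function(m, from, ang, len) {
    to <- from + len * c(sin(ang), cos(ang))
    m <- mgmorph:::raster_path(m, from, to)
    list(m = m, end = to)
  }
  m <- matrix(FALSE, 160, 160)
  s1 <- seg(m, c(20, 80), pi / 2, 70)          # trunk, 70 px
  s2 <- seg(s1$m, s1$end, pi / 2 + 0.6, 35)    # branch a, 35 px
  s3 <- seg(s2$m, s1$end, pi / 2 - 0.7, 30)    # branch b, 30 px
  tree <- mgmorph:::binary_dilate(s3$m, 1)
  truth <- 70 + 35 + 30
  got <- skeleton_metrics(tree, pixel_size_um = 1, prune_um = 2)
  expect_lt(abs(got$total_process_length_um - truth) / truth, 0.1)
  expect_equal(got$n_branches, 3L)

  # generator trees: measured skeleton tracks the generative ground truth,
  # shortened a little by rasterization + thinning of the wiggly walks
  for (s in c(2, 9, 17)) {
    cell <- make_cell_image(cell_shape_spec("ramified", noise_sd = 0,
                                            seed = s))
    got <- skeleton_metrics(cell$mask, prune_um = 2)
    truth <- cell$gen_process_length_um
    soma_allow <- 2.5 * 6  # skeleton also traverses the soma
    expect_gt(got$total_process_length_um, 0.6 * truth)
    expect_lt(got$total_process_length_um, 1.2 * truth + soma_allow)
  }
})

test_that("Sholl counts are 4 on a plus sign and 1 on a single process", {
  pm <- plus_mask(40)
  c0 <- (nrow(pm) + 1) / 2
  sh <- sholl_profile(pm, center = c(c0, c0), step_um = 4)
  inner <- sh$counts[sh$radii_um >= 8 & sh$radii_um <= 32]
  expect_true(all(inner == 4))

  bar <- matrix(FALSE, 80, 80)
  bar[40:41, 10:70] <- TRUE
  sh1 <- sholl_profile(bar, center = c(40.5, 12), step_um = 4)
  expect_equal(max(sh1$counts), 1)
  expect_error(sholl_profile(pm, center = c(-5, 2)), "outside")
})

test_that("cell body area matches opening-resistant soma geometry", {
  # disc soma r = 10 with thin processes
  m <- disc_mask(10, 81)
  m[41, 1:80] <- TRUE
  m[1:80, 41] <- TRUE
  a <- cell_body_area(m, pixel_size_um = 1, opening_radius_um = 2)
  expect_lt(abs(a - pi * 100) / (pi * 100), 0.1)
  expect_error(soma_mask(matrix(c(rep(FALSE, 12), TRUE, rep(FALSE, 12)),
                                5, 5), opening_radius_um = 3),
               "opening")
})

test_that("profiles are scale-equivariant and rotation-robust", {
  cell <- make_cell_image(cell_shape_spec("ramified", seed = 8))
  m <- cell$mask$pixels
  p1 <- morphometric_profile(cell_mask(m, 1, validate = FALSE))
  # same pixel grid at double the physical pixel size; the micrometer-valued
  # tuning parameters scale along (dimensional consistency)
  p2 <- morphometric_profile(cell_mask(m, 2, validate = FALSE),
                             sholl_step_um = 4, prune_um = 4,
                             opening_radius_um = 4)
  lengths_ <- c("cell_perimeter_um", "convex_hull_perimeter_um",
                "total_process_length_um", "max_process_length_um",
                "mean_process_length_um")
  areas_ <- c("cell_area_um2", "convex_hull_area_um2", "cell_body_area_um2")
  dimless <- c("fractal_dimension", "lacunarity", "density", "roughness",
               "convex_hull_circularity", "cell_circularity", "straightness")
  for (f in lengths_) expect_equal(p2[[f]], 2 * p1[[f]], tolerance = 1e-10)
  for (f in areas_) expect_equal(p2[[f]], 4 * p1[[f]], tolerance = 1e-10)
  for (f in dimless) expect_equal(p2[[f]], p1[[f]], tolerance = 1e-10)
  expect_equal(p2$sholl_max_counts, p1$sholl_max_counts)

  # 90-degree rotation: discretization-level changes only.  Branch
  # decomposition after thinning is the one orientation-sensitive step, so
  # the per-branch statistics (max/mean branch length) get a wider band.
  rot <- t(m)[ncol(m):1, ]
  p3 <- morphometric_profile(cell_mask(rot, 1, validate = FALSE))
  robust <- setdiff(names(p1), c("sholl_max_counts",
                                 "max_process_length_um",
                                 "mean_process_length_um"))
  for (f in robust) {
    expect_lt(abs(p3[[f]] - p1[[f]]) / abs(p1[[f]]), 0.05)
  }
  for (f in c("max_process_length_um", "mean_process_length_um")) {
    expect_lt(abs(p3[[f]] - p1[[f]]) / abs(p1[[f]]), 0.25)
  }
  expect_lte(abs(p3$sholl_max_counts - p1$sholl_max_counts), 1)
})
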