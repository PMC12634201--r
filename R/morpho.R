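# Morphometric features of a single microglial mask.  Sixteen parameters
# are computed per cell: box-counting fractal dimension, gliding-box
# lacunarity, cell/convex-hull area, perimeter and circularity, density,
# roughness, skeleton process lengths and straightness, Sholl maximum
# intersection count, and cell body area.

#' Canonical feature names
#'
#' The 16 morphometric parameters, in canonical order.
#' @return Character vector of length 16.
#' @export
morph_features <- function() {
  c("fractal_dimension", "lacunarity", "cell_area_um2",
    "convex_hull_area_um2", "density", "cell_perimeter_um",
    "convex_hull_perimeter_um", "roughness", "convex_hull_circularity",
    "cell_circularity", "total_process_length_um", "max_process_length_um",
    "mean_process_length_um", "sholl_max_counts", "straightness",
    "cell_body_area_um2")
}

# Geometric ladder of box sizes: powers of 2 from 2 px up to min(h, w)/4.
box_ladder <- function(dims, min_points = 4) {
  mx <- min(dims) / 4
  sizes <- 2^seq_len(30)
  sizes <- sizes[sizes <= mx]
  if (length(sizes) < min_points) {
    stop(sprintf(
      "mask too small for box counting (%d x %d px; need >= %d ladder points)",
      dims[1], dims[2], min_points), call. = FALSE)
  }
  sizes
}

# Boundary pixels of the foreground: foreground pixels with at least one
# 4-neighbor in the background (image border counts as background).
outline_pixels <- function(mask) {
  interior <- mask &
    shift_mat(mask, 1, 0, FALSE) & shift_mat(mask, -1, 0, FALSE) &
    shift_mat(mask, 0, 1, FALSE) & shift_mat(mask, 0, -1, FALSE)
  mask & !interior
}

#' Box-counting fractal dimension
#'
#' Slope of the least-squares fit of `log N(s)` against `log(1/s)` over a
#' geometric ladder of box sizes, where `N(s)` counts boxes of side `s`
#' containing at least one pixel of the measured set.  By default the
#' measured set is the cell outline (boundary pixels), the usual choice for
#' contour complexity; `mode = "filled"` measures the filled mask instead.
#'
#' @param mask A [cell_mask] or logical matrix.
#' @param mode `"outline"` (default) or `"filled"`.
#' @return Dimensionless fractal dimension (about 1 for smooth curves, up
#'   to 2 for plane-filling sets).
#' @export
fractal_dimension <- function(mask, mode = c("outline", "filled")) {
  mode <- match.arg(mode)
  m <- if (inherits(mask, "cell_mask")) mask$pixels else mask
  if (!any(m)) stop("mask is empty", call. = FALSE)
  sizes <- box_ladder(dim(m))
  set <- if (mode == "outline") outline_pixels(m) else m
  idx <- which(set, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    b <- (idx - 1L) %/% as.integer(s)
    nrow(unique(b))
  }, 0)
  unname(stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[2])
}

#' Gliding-box lacunarity
#'
#' For each box size `r` on the ladder, a box of side `r` glides over every
#' position fully inside the image; with box masses `m_r`,
#' `Lambda(r) = var(m_r) / mean(m_r)^2 + 1` (population variance).  The
#' scalar result is the mean of `Lambda(r)` over the ladder.  A fully
#' filled image gives exactly 1 at every scale; gappy, heterogeneous masks
#' give values well above 1.
#'
#' @param mask A [cell_mask] or logical matrix.
#' @param sizes Optional explicit box sizes (defaults to the standard
#'   ladder).
#' @return `lacunarity()`: scalar lacunarity. `lacunarity_profile()`: one
#'   value per box size.
#' @export
lacunarity <- function(mask, sizes = NULL) {
  mean(lacunarity_profile(mask, sizes))
}

#' @rdname lacunarity
#' @export
lacunarity_profile <- function(mask, sizes = NULL) {
  m <- if (inherits(mask, "cell_mask")) mask$pixels else mask
  if (!any(m)) stop("mask is empty", call. = FALSE)
  if (is.null(sizes)) sizes <- box_ladder(dim(m))
  nr <- nrow(m); nc <- ncol(m)
  # integral image with leading zero row/col
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(m * 1, 2, cumsum), 1, cumsum) |> t()
  vapply(sizes, function(s) {
    i <- seq_len(nr - s + 1); j <- seq_len(nc - s + 1)
    masses <- S[i + s, j + s, drop = FALSE] - S[i, j + s, drop = FALSE] -
      S[i + s, j, drop = FALSE] + S[i, j, drop = FALSE]
    mu <- mean(masses)
    if (mu == 0) return(NA_real_)
    mean((masses - mu)^2) / mu^2 + 1
  }, 0)
}

#' Cell and convex hull shape metrics
#'
#' Computes the eight area/perimeter-derived parameters from a cell mask:
#' cell area (foreground pixel count), cell perimeter (length of the
#' lightly smoothed marching-squares outline polygon), convex hull area and
#' perimeter (Shoelace area / polygon length of the hull of the outline),
#' circularity `4*pi*A/P^2` for cell and hull, density (cell area / hull
#' area) and roughness (cell perimeter / hull perimeter).  Lengths are in
#' micrometers and areas in square micrometers via `pixel_size_um`.
#'
#' @param mask A [cell_mask] or logical matrix.
#' @param pixel_size_um Pixel size (ignored when `mask` is a [cell_mask]).
#' @param smooth_window Contour smoothing window in vertices (odd; default
#'   3).  Window 3 keeps a rasterized disc's circularity within 2% of 1
#'   while leaving polygonal shapes essentially unsmoothed.
#' @return Named list with the eight metrics.
#' @export
hull_and_shape_metrics <- function(mask, pixel_size_um = 1,
                                   smooth_window = 3) {
  cm <- as_cell_mask(mask, pixel_size_um)
  m <- cm$pixels
  psz <- cm$pixel_size_um
  if (sum(m) < 4) stop("mask too small for shape metrics", call. = FALSE)
  ct <- outer_contour(m, smooth_window)
  hull_idx <- grDevices::chull(ct$x, ct$y)
  hx <- ct$x[hull_idx]; hy <- ct$y[hull_idx]
  cell_area <- sum(m) * psz^2
  cell_perim <- polygon_perimeter(ct$x, ct$y) * psz
  hull_area <- polygon_area(hx, hy) * psz^2
  hull_perim <- polygon_perimeter(hx, hy) * psz
  list(
    cell_area_um2 = cell_area,
    convex_hull_area_um2 = hull_area,
    density = cell_area / hull_area,
    cell_perimeter_um = cell_perim,
    convex_hull_perimeter_um = hull_perim,
    roughness = cell_perim / hull_perim,
    convex_hull_circularity = 4 * pi * hull_area / hull_perim^2,
    cell_circularity = 4 * pi * cell_area / cell_perim^2
  )
}

#' Skeleton process metrics
#'
#' Skeletonizes the mask (topology-preserving thinning), decomposes the
#' skeleton into branches (maximal paths between endpoints and junction
#' points), prunes terminal spurs shorter than `prune_um`, and reports total
#' / maximum / mean branch length (micrometers; inter-pixel steps count 1
#' for 4-neighbors and sqrt(2) for diagonals) plus straightness: the
#' unweighted mean over branches of end-to-end Euclidean distance divided
#' by branch path length.
#'
#' @param mask A [cell_mask] or logical matrix.
#' @param pixel_size_um Pixel size (ignored when `mask` is a [cell_mask]).
#' @param prune_um Terminal spurs shorter than this are discarded
#'   (default 2).
#' @return Named list: `total_process_length_um`, `max_process_length_um`,
#'   `mean_process_length_um`, `straightness`, `n_branches`.
#' @export
skeleton_metrics <- function(mask, pixel_size_um = 1, prune_um = 2) {
  cm <- as_cell_mask(mask, pixel_size_um)
  psz <- cm$pixel_size_um
  skel <- skeletonize(cm$pixels)
  degenerate <- list(total_process_length_um = 0,
                     max_process_length_um = 0,
                     mean_process_length_um = 0, straightness = 1,
                     n_branches = 0L)
  if (!any(skel)) {
    warning("empty skeleton; zero-length result", call. = FALSE)
    return(degenerate)
  }
  skel <- prune_spurs(skel, prune_um / psz)
  br <- skeleton_branches(skeleton_graph(skel))
  if (nrow(br) == 0L) {
    # compact blob whose skeleton collapses to a point: no measurable
    # processes; a degenerate path carries no tortuosity
    return(degenerate)
  }
  len <- br$length * psz
  st <- br$euclid / br$length
  st <- st[is.finite(st)]
  list(
    total_process_length_um = sum(len),
    max_process_length_um = max(len),
    mean_process_length_um = mean(len),
    straightness = if (length(st)) min(mean(st), 1) else 1,
    n_branches = nrow(br)
  )
}

#' Soma (cell body) detection
#'
#' The soma is taken as the largest connected component surviving a
#' morphological opening with a disc whose radius removes thin processes.
#'
#' @param mask A [cell_mask] or logical matrix.
#' @param pixel_size_um Pixel size (ignored when `mask` is a [cell_mask]).
#' @param opening_radius_um Disc radius of the opening, micrometers
#'   (default 2).
#' @return `list(mask = logical matrix, centroid = c(row, col))`.
#' @export
soma_mask <- function(mask, pixel_size_um = 1, opening_radius_um = 2) {
  cm <- as_cell_mask(mask, pixel_size_um)
  r_px <- max(1, opening_radius_um / cm$pixel_size_um)
  opened <- binary_open(cm$pixels, r_px)
  if (!any(opened)) {
    stop("soma detection failed: opening erased the whole mask",
         call. = FALSE)
  }
  # 4-connectivity: a 4-connected region has a single outer contour loop,
  # so the Shoelace area downstream is well defined in any orientation
  lab <- label_components(opened, 4)
  sizes <- tabulate(lab[lab > 0])
  soma <- lab == which.max(sizes)
  idx <- which(soma, arr.ind = TRUE)
  list(mask = soma, centroid = c(mean(idx[, 1]), mean(idx[, 2])))
}

#' Cell body area via the Shoelace theorem
#'
#' Detects the soma ([soma_mask]), extracts its outer contour polygon, and
#' measures the polygon area with the Shoelace formula, converted to square
#' micrometers.
#'
#' @inheritParams soma_mask
#' @param smooth_window Contour smoothing window (default 3).
#' @return Area in square micrometers.
#' @export
cell_body_area <- function(mask, pixel_size_um = 1, opening_radius_um = 2,
                           smooth_window = 3) {
  cm <- as_cell_mask(mask, pixel_size_um)
  soma <- soma_mask(cm, opening_radius_um = opening_radius_um)
  ct <- outer_contour(soma$mask, smooth_window)
  polygon_area(ct$x, ct$y) * cm$pixel_size_um^2
}

#' Sholl profile
#'
#' Counts skeleton intersections with concentric circles around the soma:
#' for each radius `r = step, 2*step, ...`, the number of connected runs of
#' skeleton pixels crossing the circle (8-connected groups of skeleton
#' pixels within a one-pixel band around the circle).
#'
#' @param mask A [cell_mask] or logical matrix.
#' @param center `(row, col)` circle center; default: soma centroid.
#' @param step_um Radial step in micrometers (default 2).
#' @param pixel_size_um Pixel size (ignored when `mask` is a [cell_mask]).
#' @return `list(radii_um, counts, center)`; `max(counts)` (0 when no radii
#'   fit) is the `sholl_max_counts` feature.
#' @export
sholl_profile <- function(mask, center = NULL, step_um = 2,
                          pixel_size_um = 1) {
  cm <- as_cell_mask(mask, pixel_size_um)
  psz <- cm$pixel_size_um
  if (is.null(center)) {
    center <- soma_mask(cm)$centroid
  }
  if (center[1] < 1 || center[1] > nrow(cm$pixels) ||
      center[2] < 1 || center[2] > ncol(cm$pixels)) {
    stop("Sholl center lies outside the image", call. = FALSE)
  }
  skel <- skeletonize(cm$pixels)
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(radii_um = numeric(0), counts = integer(0), center = center))
  }
  d_um <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2) * psz
  r_max <- max(d_um)
  if (r_max < step_um) {
    return(list(radii_um = numeric(0), counts = integer(0), center = center))
  }
  radii <- seq(step_um, r_max, by = step_um)
  band <- 0.75 * psz # half-width of the circle band, in um
  counts <- vapply(radii, function(r) {
    sel <- abs(d_um - r) <= band
    if (!any(sel)) return(0L)
    ring <- matrix(FALSE, nrow(cm$pixels), ncol(cm$pixels))
    ring[idx[sel, , drop = FALSE]] <- TRUE
    n_components(ring, 8)
  }, 0L)
  list(radii_um = radii, counts = counts, center = center)
}

#' Full morphometric profile of one cell
#'
#' Computes all 16 parameters for a [cell_mask].  Masks smaller than 64 px
#' on a side are zero-padded so the box-counting ladder has at least four
#' points.
#'
#' @param mask A [cell_mask] or logical matrix.
#' @param pixel_size_um Pixel size (ignored when `mask` is a [cell_mask]).
#' @param sholl_step_um Sholl radial step (default 2).
#' @param prune_um Skeleton spur-pruning threshold (default 2).
#' @param opening_radius_um Soma opening radius (default 2).
#' @param fd_mode Fractal dimension on the `"outline"` (default) or
#'   `"filled"` set.
#' @return One-row data.frame with the 16 columns of [morph_features()].
#' @export
morphometric_profile <- function(mask, pixel_size_um = 1, sholl_step_um = 2,
                                 prune_um = 2, opening_radius_um = 2,
                                 fd_mode = "outline") {
  cm <- as_cell_mask(mask, pixel_size_um)
  m <- cm$pixels
  # standardize the frame: crop to the tight bounding box (+2 px margin),
  # then center-pad to >= 64 px per side so the box-size ladder has at
  # least four points and the scale-sensitive features (lacunarity) are
  # not driven by arbitrary canvas size
  rs <- range(which(rowSums(m) > 0)); cs <- range(which(colSums(m) > 0))
  m <- m[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
  tgt <- rep(max(dim(m) + 4L, 64L), 2L)
  p <- matrix(FALSE, tgt[1], tgt[2])
  r0 <- (tgt[1] - nrow(m)) %/% 2
  c0 <- (tgt[2] - ncol(m)) %/% 2
  p[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  cm <- cell_mask(p, cm$pixel_size_um, cm$offset, validate = FALSE)
  # lacunarity over the tight bounding box: measured there it indexes the
  # gap structure of the arbor itself (ramified/rod high, compact blobs
  # near 1) instead of the emptiness of the surrounding canvas
  lac_sizes <- 2^seq_len(30)
  lac_sizes <- lac_sizes[lac_sizes <= min(dim(m)) / 4]
  if (length(lac_sizes) < 2) lac_sizes <- c(2, 4)[c(2, 4) <= min(dim(m)) / 2]
  if (length(lac_sizes) == 0) {
    stop("mask too small for lacunarity", call. = FALSE)
  }
  lac <- mean(lacunarity_profile(m, lac_sizes))

  shape <- hull_and_shape_metrics(cm)
  skel <- skeleton_metrics(cm, prune_um = prune_um)
  soma <- soma_mask(cm, opening_radius_um = opening_radius_um)
  sholl <- sholl_profile(cm, center = soma$centroid,
                         step_um = sholl_step_um)
  out <- data.frame(
    fractal_dimension = fractal_dimension(cm, mode = fd_mode),
    lacunarity = lac,
    cell_area_um2 = shape$cell_area_um2,
    convex_hull_area_um2 = shape$convex_hull_area_um2,
    density = shape$density,
    cell_perimeter_um = shape$cell_perimeter_um,
    convex_hull_perimeter_um = shape$convex_hull_perimeter_um,
    roughness = shape$roughness,
    convex_hull_circularity = shape$convex_hull_circularity,
    cell_circularity = shape$cell_circularity,
    total_process_length_um = skel$total_process_length_um,
    max_process_length_um = skel$max_process_length_um,
    mean_process_length_um = skel$mean_process_length_um,
    sholl_max_counts = if (length(sholl$counts)) max(sholl$counts) else 0L,
    straightness = skel$straightness,
    cell_body_area_um2 = cell_body_area(
      cm, opening_radius_um = opening_radius_um)
  )
  out[, morph_features()]
}
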