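# Image preparation: maximum projection, background correction, Otsu
# binarization and single-cell isolation.  Mirrors the preprocessing used
# for confocal microglia stacks: z-stacks are flattened to 2D, the
# low-frequency background is removed, the image is thresholded, and
# nonoverlapping single cells are cropped out for morphometry.

#' Maximum intensity projection
#'
#' Flattens a z-stack to 2D by taking, at every pixel, the maximum intensity
#' over all z planes.
#'
#' @param stack An [image_stack] (or a bare 3D `[row, col, z]` array).
#' @return A numeric matrix.
#' @export
max_project <- function(stack) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (is.matrix(v)) return(v)
  if (!is.array(v) || length(dim(v)) != 3L || dim(v)[3] < 1L) {
    stop("`stack` must contain at least one z plane", call. = FALSE)
  }
  out <- v[, , 1]
  nz <- dim(v)[3]
  if (nz > 1) for (k in 2:nz) out <- pmax(out, v[, , k])
  out
}

#' Background correction
#'
#' Estimates the large-scale background as a wide Gaussian blur of the image
#' and subtracts it, clipping at zero.  Optionally applies a band-pass
#' (difference-of-Gaussians) contour-enhancement stage, which suppresses
#' both the residual low-frequency background and single-pixel noise.
#'
#' @param image Numeric matrix.
#' @param pixel_size_um Pixel size in micrometers.
#' @param gauss_sigma_um Standard deviation of the background Gaussian, in
#'   micrometers (default 25).
#' @param bandpass Apply the optional band-pass stage (default FALSE).
#' @param band_um Length-2 vector: the fine and coarse smoothing scales of
#'   the band-pass, in micrometers.
#' @return Background-corrected numeric matrix (>= 0).
#' @export
correct_background <- function(image, pixel_size_um = 1,
                               gauss_sigma_um = 25, bandpass = FALSE,
                               band_um = c(1, 10)) {
  stop_if_not_scalar_pos(gauss_sigma_um, "gauss_sigma_um")
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  sigma_px <- gauss_sigma_um / pixel_size_um
  bg <- gaussian_blur(image, sigma_px)
  out <- pmax(image - bg, 0)
  if (bandpass) {
    lo <- gaussian_blur(out, max(band_um[1] / pixel_size_um, 0.5))
    hi <- gaussian_blur(out, max(band_um[2] / pixel_size_um, 1))
    out <- pmax(lo - hi, 0)
  }
  out
}

#' Otsu thresholding
#'
#' Computes the threshold maximizing between-class variance of the 256-bin
#' intensity histogram and returns it together with the binary mask
#' (`image > threshold`).
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return `list(threshold = , mask = )`.
#' @export
binarize_otsu <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("Otsu threshold undefined: image has a degenerate histogram",
         call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  p <- h / sum(h)
  omega <- cumsum(p)                 # class-0 mass up to and incl. bin t
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance for cut after bin t = 1..n_bins-1
  t_idx <- seq_len(n_bins - 1)
  w0 <- omega[t_idx]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[t_idx][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  t_best <- which.max(sigma_b)
  threshold <- breaks[t_best + 1]
  list(threshold = threshold, mask = image > threshold)
}

#' Isolate nonoverlapping single cells
#'
#' Labels connected components of a binary section mask and filters them the
#' way single-cell morphometry requires: components touching the image
#' border are discarded, components outside the configured area bounds are
#' discarded, and components whose (margin-expanded) bounding boxes overlap
#' are discarded as "overlapping".  Up to `n_target` survivors are returned,
#' largest first (ties broken by bounding-box row then column), each cropped
#' with padding into its own [cell_mask].
#'
#' @param mask Logical matrix (binarized section).
#' @param n_target Maximum number of cells to return (default 20).
#' @param pixel_size_um Pixel size in micrometers.
#' @param area_bounds_um2 Permissible component area, in square micrometers
#'   (default `c(50, 5000)`).
#' @param bbox_margin_px Margin added around bounding boxes before the
#'   overlap test (default 2).
#' @param pad_px Background padding around each crop (default 8).
#' @return List of [cell_mask] objects (possibly empty, with a warning).
#' @export
isolate_cells <- function(mask, n_target = 20, pixel_size_um = 1,
                          area_bounds_um2 = c(50, 5000),
                          bbox_margin_px = 2, pad_px = 8) {
  if (!any(mask)) stop("section mask is empty", call. = FALSE)
  lab <- label_components(mask, 8)
  k <- max(lab)
  if (k == 0L) stop("section mask is empty", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(lab > 0)
  comp <- lab[idx]
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  stats_df <- data.frame(
    comp = seq_len(k),
    area_px = as.vector(tabulate(comp, nbins = k)),
    rmin = as.vector(tapply(ri, comp, min)),
    rmax = as.vector(tapply(ri, comp, max)),
    cmin = as.vector(tapply(ci, comp, min)),
    cmax = as.vector(tapply(ci, comp, max))
  )
  stats_df$area_um2 <- stats_df$area_px * pixel_size_um^2
  keep <- stats_df$rmin > 1 & stats_df$cmin > 1 &
    stats_df$rmax < nr & stats_df$cmax < nc &
    stats_df$area_um2 >= area_bounds_um2[1] &
    stats_df$area_um2 <= area_bounds_um2[2]
  cand <- stats_df[keep, , drop = FALSE]
  if (nrow(cand) > 1) {
    m <- bbox_margin_px
    overlap <- rep(FALSE, nrow(cand))
    for (i in seq_len(nrow(cand) - 1)) {
      for (j in (i + 1):nrow(cand)) {
        if (cand$rmin[i] - m <= cand$rmax[j] + m &&
            cand$rmax[i] + m >= cand$rmin[j] - m &&
            cand$cmin[i] - m <= cand$cmax[j] + m &&
            cand$cmax[i] + m >= cand$cmin[j] - m) {
          overlap[i] <- overlap[j] <- TRUE
        }
      }
    }
    cand <- cand[!overlap, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    warning("no isolated cells survived filtering", call. = FALSE)
    return(list())
  }
  ord <- order(-cand$area_px, cand$rmin, cand$cmin)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[seq_len(min(n_target, nrow(cand))), , drop = FALSE]
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    sub <- lab[cc$rmin:cc$rmax, cc$cmin:cc$cmax, drop = FALSE] == cc$comp
    p <- pad_px
    padded <- matrix(FALSE, nrow(sub) + 2 * p, ncol(sub) + 2 * p)
    padded[p + seq_len(nrow(sub)), p + seq_len(ncol(sub))] <- sub
    out[[i]] <- cell_mask(padded, pixel_size_um,
                          offset = c(cc$rmin - p, cc$cmin - p),
                          validate = FALSE)
  }
  out
}
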