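# Perilesional quantifications: cell density within a fixed region of
# interest (ROI) and immunopositive-area fraction.  The canonical ROI is a
# 500 x 500 um square centered on the injury tip (area 0.25 mm^2).

#' Region-of-interest specification
#'
#' @param center `(row, col)` pixel coordinates of the ROI center.
#' @param width_um,height_um ROI extent in micrometers (default 500 x 500).
#' @param pixel_size_um Pixel size in micrometers.
#' @return List of class `roi_spec` with the half-open pixel bounds
#'   (`r0 <= r < r1`, `c0 <= c < c1`).
#' @export
roi_spec <- function(center, width_um = 500, height_um = 500,
                     pixel_size_um = 1) {
  stop_if_not_scalar_pos(width_um, "width_um")
  stop_if_not_scalar_pos(height_um, "height_um")
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  h_px <- height_um / pixel_size_um
  w_px <- width_um / pixel_size_um
  structure(
    list(center = center, width_um = width_um, height_um = height_um,
         pixel_size_um = pixel_size_um,
         r0 = center[1] - h_px / 2, r1 = center[1] + h_px / 2,
         c0 = center[2] - w_px / 2, c1 = center[2] + w_px / 2),
    class = "roi_spec")
}

check_roi_inside <- function(roi, dims) {
  if (roi$r0 < 0.5 || roi$c0 < 0.5 ||
      roi$r1 > dims[1] + 0.5 || roi$c1 > dims[2] + 0.5) {
    stop("ROI exceeds image bounds", call. = FALSE)
  }
  invisible(roi)
}

#' Cell density within an ROI
#'
#' Counts centroids inside the ROI (half-open bounds: left/top edges
#' inclusive, right/bottom exclusive, so tiled ROIs never double-count) and
#' divides by the ROI area in mm^2.  The default 500 x 500 um ROI has area
#' 0.25 mm^2.
#'
#' @param centroids data.frame with columns `row` and `col` (pixel
#'   coordinates).
#' @param roi An [roi_spec].
#' @param image_dims Optional `(rows, cols)` of the source image; when
#'   given, an ROI outside the image is an error.
#' @return List: `n_cells`, `area_mm2`, `density_mm2`.
#' @export
roi_cell_density <- function(centroids, roi, image_dims = NULL) {
  stopifnot(inherits(roi, "roi_spec"))
  if (!is.null(image_dims)) check_roi_inside(roi, image_dims)
  inside <- centroids$row >= roi$r0 & centroids$row < roi$r1 &
    centroids$col >= roi$c0 & centroids$col < roi$c1
  area_mm2 <- (roi$width_um / 1000) * (roi$height_um / 1000)
  list(n_cells = sum(inside), area_mm2 = area_mm2,
       density_mm2 = sum(inside) / area_mm2)
}

#' Immunopositive area fraction within an ROI
#'
#' Percentage of ROI pixels whose intensity exceeds the threshold; the
#' threshold is either a fixed intensity (emulating a manually chosen
#' cutoff, recorded in the output) or `"otsu"`.
#'
#' @param image Numeric intensity matrix.
#' @param roi An [roi_spec].
#' @param threshold Numeric intensity or `"otsu"` (default).
#' @return List: `percent_positive`, `threshold`, `n_roi_px`.
#' @export
positive_area_fraction <- function(image, roi, threshold = "otsu") {
  stopifnot(inherits(roi, "roi_spec"))
  check_roi_inside(roi, dim(image))
  rows <- seq_len(nrow(image))
  cols <- seq_len(ncol(image))
  rsel <- rows >= roi$r0 & rows < roi$r1
  csel <- cols >= roi$c0 & cols < roi$c1
  sub <- image[rsel, csel, drop = FALSE]
  thr <- if (identical(threshold, "otsu")) {
    binarize_otsu(sub)$threshold
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  list(percent_positive = 100 * mean(sub > thr), threshold = thr,
       n_roi_px = length(sub))
}
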