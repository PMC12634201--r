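# Core data containers.  Images are base R matrices (rows = y, cols = x);
# stacks are 3D arrays with the z planes along the third dimension.

#' Construct an image stack
#'
#' A z-stack of grayscale planes with a physical pixel size.  Stored as a
#' 3D array `[row, col, z]`.
#'
#' @param voxels 3D numeric array `[row, col, z]`, or a matrix (one plane).
#' @param pixel_size_um Physical pixel size in micrometers (> 0).
#' @param bit_depth Nominal bit depth of the acquisition (informational).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_um, bit_depth = 8L) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L || dim(voxels)[3] < 1L) {
    stop("`voxels` must be a [row, col, z] array with >= 1 plane", call. = FALSE)
  }
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' Construct a single-cell binary mask
#'
#' The substrate of all morphometry: a 2D logical matrix holding exactly one
#' 8-connected foreground component, with its physical pixel size and the
#' offset of the crop origin in section coordinates.
#'
#' @param pixels Logical matrix (TRUE = cell).
#' @param pixel_size_um Physical pixel size in micrometers (> 0).
#' @param offset Integer `(row, col)` of the crop origin in the source
#'   section (1-based); `c(1, 1)` for stand-alone masks.
#' @param validate Check the single-component invariant (default TRUE).
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(pixels, pixel_size_um, offset = c(1L, 1L),
                      validate = TRUE) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  if (!any(pixels)) stop("cell mask is empty", call. = FALSE)
  if (validate && n_components(pixels, 8) != 1L) {
    stop("cell mask must contain exactly one connected component",
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         offset = as.integer(offset)),
    class = "cell_mask"
  )
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d px (%.3g um/px), %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              sum(x$pixels)))
  invisible(x)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d plane(s), %.3g um/px\n",
              d[1], d[2], d[3], x$pixel_size_um))
  invisible(x)
}

# Coerce a plain logical matrix or cell_mask argument to cell_mask.
as_cell_mask <- function(x, pixel_size_um = 1) {
  if (inherits(x, "cell_mask")) return(x)
  cell_mask(x, pixel_size_um)
}
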