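# Plain-text I/O: pose-estimation keypoint tables in the DeepLabCut CSV
# dialect (three header rows: scorer / bodyparts / coords), portable
# grayscale images as ASCII PGM (P2), and feature tables as CSV.

#' Write a trajectory as a DeepLabCut-dialect CSV
#'
#' Three header rows (`scorer`, `bodyparts`, `coords`) above one row per
#' frame, with `x`, `y`, `likelihood` columns per bodypart and a leading
#' frame-index column.
#'
#' @param traj A [trajectory].
#' @param path Output file path.
#' @param scorer Scorer name written in the first header row.
#' @export
write_dlc_csv <- function(traj, path, scorer = "synthetic") {
  bps <- TRAJ_BODYPARTS
  hdr1 <- c("scorer", rep(scorer, 3 * length(bps)))
  hdr2 <- c("bodyparts", rep(bps, each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(bps)))
  cols <- as.vector(vapply(bps, function(b)
    paste0(b, c("_x", "_y", "_conf")), character(3)))
  body <- cbind(seq_len(nrow(traj)) - 1L,
                as.matrix(as.data.frame(traj)[, cols]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","),
               paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  utils::write.table(body, con, sep = ",", col.names = FALSE,
                     row.names = FALSE)
}

#' Read a DeepLabCut-dialect CSV into a trajectory
#'
#' @param path CSV path (3 header rows as written by [write_dlc_csv()] or
#'   by DeepLabCut itself).
#' @param fps Frame rate of the recording.
#' @param cm_per_px Spatial calibration.
#' @param arena_cm Arena side length (default 40).
#' @return A [trajectory].
#' @export
read_dlc_csv <- function(path, fps, cm_per_px, arena_cm = 40) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  bps <- as.character(hdr[2, -1])
  coords <- as.character(hdr[3, -1])
  dat <- utils::read.csv(path, header = FALSE, skip = 3)
  coord_map <- c(x = "x", y = "y", likelihood = "conf")
  cols <- paste0(bps, "_", coord_map[coords])
  frames <- as.data.frame(dat[, -1])
  names(frames) <- cols
  trajectory(frames, fps = fps, cm_per_px = cm_per_px, arena_cm = arena_cm)
}

#' Write a matrix as an ASCII PGM (P2) image
#'
#' Portable text format for grayscale images; intensities are rounded and
#' clipped to `[0, maxval]`.
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @param maxval Maximum gray value (default 255).
#' @export
write_pgm <- function(image, path, maxval = 255) {
  v <- pmin(pmax(round(image), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)),
               as.character(maxval)), con)
  utils::write.table(v, con, sep = " ", col.names = FALSE,
                     row.names = FALSE)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path PGM path.
#' @return Numeric matrix.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("not an ASCII PGM (P2) file", call. = FALSE)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

# Deterministic CSV writer used by the pipeline outputs: fixed field order,
# no row names, fixed significant digits so reruns are byte-identical.
write_csv_det <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  utils::write.csv(df, path, row.names = FALSE)
}
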