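# Open-field behavior: locomotion metrics, occupancy maps, straight-walk
# segment selection, cosine-fit gait amplitude, and grip-strength
# normalization.  Input is a per-frame keypoint table (nose, hip, tail
# base) as produced by markerless pose estimation, with a confidence
# ("likelihood") column per keypoint.

TRAJ_BODYPARTS <- c("nose", "hip", "tail_base")

#' Construct a trajectory
#'
#' Per-frame keypoint coordinates with confidences, frame rate and spatial
#' calibration.
#'
#' @param frames data.frame with columns `<bp>_x`, `<bp>_y`, `<bp>_conf`
#'   for each bodypart in `nose`, `hip`, `tail_base` (pixel units).
#' @param fps Frames per second.
#' @param cm_per_px Centimeters per pixel.
#' @param arena_cm Arena side length in centimeters (default 40).
#' @return data.frame of class `trajectory` with a prepended `t` column
#'   and `fps` / `cm_per_px` / `arena_cm` attributes.
#' @export
trajectory <- function(frames, fps, cm_per_px, arena_cm = 40) {
  stop_if_not_scalar_pos(fps, "fps")
  stop_if_not_scalar_pos(cm_per_px, "cm_per_px")
  need <- as.vector(outer(TRAJ_BODYPARTS, c("x", "y", "conf"), paste,
                          sep = "_"))
  missing <- setdiff(need, names(frames))
  if (length(missing)) {
    stop("trajectory missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conf_cols <- paste0(TRAJ_BODYPARTS, "_conf")
  for (cc in conf_cols) {
    if (any(frames[[cc]] < 0 | frames[[cc]] > 1, na.rm = TRUE)) {
      stop("confidences must lie in [0, 1]", call. = FALSE)
    }
  }
  frames <- frames[, need]
  out <- cbind(t = (seq_len(nrow(frames)) - 1) / fps, frames)
  structure(out, fps = fps, cm_per_px = cm_per_px, arena_cm = arena_cm,
            class = c("trajectory", "data.frame"))
}

# Confidence filtering + gap interpolation for one keypoint.  Frames below
# the confidence threshold become NA and gaps of at most `max_gap` frames
# are linearly interpolated; longer gaps stay NA.
filter_keypoint <- function(x, y, conf, conf_threshold = 0.9, max_gap = 5) {
  bad <- conf < conf_threshold
  x[bad] <- NA; y[bad] <- NA
  fill <- function(v) {
    if (!anyNA(v)) return(v)
    idx <- which(!is.na(v))
    if (length(idx) < 2) return(v)
    runs <- rle(is.na(v))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    out <- v
    for (k in which(runs$values)) {
      if (runs$lengths[k] <= max_gap && starts[k] > 1 &&
          ends[k] < length(v)) {
        s <- starts[k] - 1; e <- ends[k] + 1
        out[starts[k]:ends[k]] <-
          stats::approx(c(s, e), v[c(s, e)], xout = starts[k]:ends[k])$y
      }
    }
    out
  }
  list(x = fill(x), y = fill(y))
}

# Median-smoothed, confidence-filtered positions (cm) of one keypoint.
keypoint_cm <- function(traj, bodypart = "hip", conf_threshold = 0.9,
                        max_gap = 5, smooth_k = 3) {
  cmpx <- attr(traj, "cm_per_px")
  kp <- filter_keypoint(traj[[paste0(bodypart, "_x")]],
                        traj[[paste0(bodypart, "_y")]],
                        traj[[paste0(bodypart, "_conf")]],
                        conf_threshold, max_gap)
  ok <- !is.na(kp$x) & !is.na(kp$y)
  x <- kp$x * cmpx; y <- kp$y * cmpx
  if (smooth_k > 1 && sum(ok) >= smooth_k) {
    x[ok] <- stats::runmed(x[ok], smooth_k, endrule = "keep")
    y[ok] <- stats::runmed(y[ok], smooth_k, endrule = "keep")
  }
  data.frame(t = traj$t, x = x, y = y, valid = ok)
}

#' Open-field locomotion metrics
#'
#' Total distance traveled, average speed and maximum speed from the hip
#' keypoint.  Frames below the confidence threshold are dropped (gaps up to
#' `max_gap` frames linearly interpolated), positions are median-smoothed
#' over `smooth_k` frames to suppress tracking spikes, distance sums
#' consecutive displacements, average speed is distance over elapsed time,
#' and maximum speed is the largest per-frame displacement rate.
#'
#' @param traj A [trajectory].
#' @param bodypart Keypoint to track (default `"hip"`).
#' @param conf_threshold Minimum keypoint confidence (default 0.9).
#' @param max_gap Longest interpolatable gap, frames (default 5).
#' @param smooth_k Median filter width, frames (odd; default 3; 1 = raw).
#' @return List: `total_distance_cm`, `avg_speed_cm_s`, `max_speed_cm_s`,
#'   `n_valid_frames`.
#' @export
locomotion_metrics <- function(traj, bodypart = "hip", conf_threshold = 0.9,
                               max_gap = 5, smooth_k = 3) {
  kp <- keypoint_cm(traj, bodypart, conf_threshold, max_gap, smooth_k)
  kp <- kp[!is.na(kp$x), , drop = FALSE]
  if (nrow(kp) < 2) {
    stop("fewer than 2 frames above the confidence threshold", call. = FALSE)
  }
  dx <- diff(kp$x); dy <- diff(kp$y); dt <- diff(kp$t)
  step <- sqrt(dx^2 + dy^2)
  total <- sum(step)
  elapsed <- kp$t[nrow(kp)] - kp$t[1]
  list(total_distance_cm = total,
       avg_speed_cm_s = total / elapsed,
       max_speed_cm_s = max(step / dt),
       n_valid_frames = nrow(kp))
}

#' Occupancy map
#'
#' Per-bin counts of valid frames over a regular grid spanning the arena.
#' The counts over all bins sum exactly to the number of valid frames;
#' positions outside the arena are clipped into the edge bins with a
#' warning.
#'
#' @param traj A [trajectory].
#' @param n_bins Number of bins per axis (default 20).
#' @param bodypart Keypoint (default `"hip"`).
#' @param conf_threshold Minimum confidence (default 0.9).
#' @return Integer matrix `n_bins x n_bins` (rows = y bins).
#' @export
occupancy_map <- function(traj, n_bins = 20, bodypart = "hip",
                          conf_threshold = 0.9) {
  arena <- attr(traj, "arena_cm")
  kp <- keypoint_cm(traj, bodypart, conf_threshold, max_gap = 0,
                    smooth_k = 1)
  kp <- kp[kp$valid, , drop = FALSE]
  n_out <- sum(kp$x < 0 | kp$x > arena | kp$y < 0 | kp$y > arena)
  if (n_out > 0) {
    warning(sprintf("%d frame(s) outside the arena were clipped", n_out),
            call. = FALSE)
  }
  bx <- pmin(pmax(ceiling(kp$x / arena * n_bins), 1), n_bins)
  by <- pmin(pmax(ceiling(kp$y / arena * n_bins), 1), n_bins)
  m <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(bx)) m[by[i], bx[i]] <- m[by[i], bx[i]] + 1L
  m
}

# Per-frame hip speed (cm/s) and heading (rad) on smoothed positions.
speed_heading <- function(traj, conf_threshold = 0.9) {
  kp <- keypoint_cm(traj, "hip", conf_threshold, max_gap = 5, smooth_k = 3)
  fps <- attr(traj, "fps")
  dx <- c(NA, diff(kp$x)); dy <- c(NA, diff(kp$y))
  data.frame(t = kp$t, speed = sqrt(dx^2 + dy^2) * fps,
             heading = atan2(dy, dx), valid = kp$valid)
}

#' Straight-walking segment selection
#'
#' Scans all non-overlapping candidate windows of `seg_s` seconds and keeps
#' windows where the mean hip speed is at least `speed_min_cm_s` and the
#' net heading change stays within `turn_max_deg_s`.  The `n_segments` top
#' windows by straightness score (net displacement / path length) are
#' returned, ties broken by start time.
#'
#' @param traj A [trajectory].
#' @param n_segments Number of windows wanted (default 5).
#' @param seg_s Window length in seconds (default 1).
#' @param speed_min_cm_s Minimum mean speed (default 3).
#' @param turn_max_deg_s Maximum net heading change rate (default 20).
#' @return data.frame of selected windows: `start_frame`, `end_frame`,
#'   `score`; fewer than `n_segments` rows (with a warning) when the
#'   trajectory has too few qualifying windows.
#' @export
straight_walk_segments <- function(traj, n_segments = 5, seg_s = 1,
                                   speed_min_cm_s = 3, turn_max_deg_s = 20) {
  fps <- attr(traj, "fps")
  win <- round(seg_s * fps)
  n <- nrow(traj)
  if (n < n_segments * win) {
    stop("trajectory shorter than n_segments x seg_s", call. = FALSE)
  }
  sh <- speed_heading(traj)
  kp <- keypoint_cm(traj, "hip", max_gap = 5, smooth_k = 3)
  cand <- list()
  for (s in seq_len(n - win + 1)) {
    e <- s + win - 1
    sp <- sh$speed[(s + 1):e]
    if (anyNA(sp) || mean(sp) < speed_min_cm_s) next
    hd <- sh$heading[(s + 1):e]
    net_turn <- abs(atan2(sin(hd[length(hd)] - hd[1]),
                          cos(hd[length(hd)] - hd[1])))
    if (net_turn * 180 / pi > turn_max_deg_s * seg_s) next
    path <- sum(sqrt(diff(kp$x[s:e])^2 + diff(kp$y[s:e])^2))
    net <- sqrt((kp$x[e] - kp$x[s])^2 + (kp$y[e] - kp$y[s])^2)
    cand[[length(cand) + 1L]] <-
      data.frame(start_frame = s, end_frame = e,
                 score = if (path > 0) net / path else 0)
  }
  if (length(cand) == 0L) {
    warning("no qualifying straight-walk windows", call. = FALSE)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      score = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$start_frame), , drop = FALSE]
  chosen <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start_frame[i]:cand$end_frame[i]
    if (!any(used[idx])) {
      chosen[[length(chosen) + 1L]] <- cand[i, ]
      used[idx] <- TRUE
      if (length(chosen) == n_segments) break
    }
  }
  out <- do.call(rbind, chosen)
  if (nrow(out) < n_segments) {
    warning(sprintf("only %d of %d straight-walk windows found",
                    nrow(out), n_segments), call. = FALSE)
  }
  out <- out[order(out$start_frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Body segment angle time series
#'
#' Unsigned interior angle at the hip between the hip->nose and
#' hip->tail-base vectors, in degrees (0 to 180).
#'
#' @param traj A [trajectory].
#' @return Numeric vector, one angle per frame.
#' @export
segment_angles <- function(traj) {
  v1x <- traj$nose_x - traj$hip_x; v1y <- traj$nose_y - traj$hip_y
  v2x <- traj$tail_base_x - traj$hip_x; v2y <- traj$tail_base_y - traj$hip_y
  dot <- v1x * v2x + v1y * v2y
  n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
  ang <- acos(pmin(pmax(dot / (n1 * n2), -1), 1))
  ang * 180 / pi
}

#' Cosine-fit gait amplitude
#'
#' Fits `A * cos(2*pi*f*t + phi) + c` to the body-segment angle within each
#' straight-walk window by nonlinear least squares, with the frequency
#' bounded to `f_range` and initialized from the dominant peak of the
#' discrete spectrum.  The amplitude |A| of the fitted curve indexes
#' locomotor coordination.  Windows whose fit fails to converge are
#' skipped with a diagnostic.
#'
#' @param traj A [trajectory].
#' @param windows data.frame from [straight_walk_segments()] (or any
#'   `start_frame`/`end_frame` table).
#' @param f_range Frequency bounds in Hz (default `c(1, 8)`).
#' @return List: `fits` (one row per fitted window: `amplitude_deg`,
#'   `freq_hz`, `phase_rad`, `offset_deg`, `r2`) and `mean_amplitude_deg`.
#' @export
gait_amplitude <- function(traj, windows, f_range = c(1, 8)) {
  stopifnot(nrow(windows) >= 1)
  fps <- attr(traj, "fps")
  if (f_range[2] >= fps / 2) {
    stop("upper frequency bound must be below the Nyquist rate",
         call. = FALSE)
  }
  ang_all <- segment_angles(traj)
  fits <- list()
  for (i in seq_len(nrow(windows))) {
    fr <- windows$start_frame[i]:windows$end_frame[i]
    ang <- ang_all[fr]
    tt <- (seq_along(fr) - 1) / fps
    if (anyNA(ang)) next
    # spectral initialization: dominant in-band peak gives frequency and,
    # through its complex argument, the starting phase
    y <- ang - mean(ang)
    z <- stats::fft(y)
    half <- seq_len(floor(length(y) / 2)) + 1
    sp <- Mod(z)[half]
    freqs <- (half - 1) / (length(y) / fps)
    in_band <- freqs >= f_range[1] & freqs <= f_range[2]
    if (any(in_band)) {
      pk <- which(in_band)[which.max(sp[in_band])]
      f0 <- freqs[pk]
      phi0 <- Arg(z[half[pk]])
    } else {
      f0 <- mean(f_range)
      phi0 <- 0
    }
    a0 <- max(stats::sd(y) * sqrt(2), 1e-6)
    fit <- NULL
    for (phi_try in c(phi0, phi0 + pi / 2, phi0 - pi / 2, phi0 + pi)) {
      fit <- tryCatch(
        stats::nls(ang ~ A * cos(2 * pi * f * tt + phi) + c0,
                   start = list(A = a0, f = f0, phi = phi_try,
                                c0 = mean(ang)),
                   algorithm = "port",
                   lower = c(A = 0, f = f_range[1], phi = -2 * pi,
                             c0 = -360),
                   upper = c(A = 180, f = f_range[2], phi = 2 * pi,
                             c0 = 360),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      message(sprintf("gait fit did not converge for window %d; skipped", i))
      next
    }
    cf <- stats::coef(fit)
    resid <- stats::resid(fit)
    ss_tot <- sum((ang - mean(ang))^2)
    r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
    fits[[length(fits) + 1L]] <- data.frame(
      window = i, amplitude_deg = abs(cf[["A"]]), freq_hz = cf[["f"]],
      phase_rad = cf[["phi"]], offset_deg = cf[["c0"]], r2 = r2)
  }
  fits <- if (length(fits)) do.call(rbind, fits) else
    data.frame(window = integer(0), amplitude_deg = numeric(0),
               freq_hz = numeric(0), phase_rad = numeric(0),
               offset_deg = numeric(0), r2 = numeric(0))
  rownames(fits) <- NULL
  list(fits = fits,
       mean_amplitude_deg = if (nrow(fits)) mean(fits$amplitude_deg)
       else NA_real_)
}

#' Grip-strength index
#'
#' Mean of the trial forces normalized by body weight in grams.
#'
#' @param forces Numeric vector of trial force readings (typically 3).
#' @param body_weight_g Body weight in grams.
#' @return Scalar normalized grip strength.
#' @export
grip_index <- function(forces, body_weight_g) {
  if (any(!is.finite(forces)) || any(forces <= 0)) {
    stop("forces must be positive", call. = FALSE)
  }
  stop_if_not_scalar_pos(body_weight_g, "body_weight_g")
  mean(forces) / body_weight_g
}
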