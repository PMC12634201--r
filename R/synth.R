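# Seeded synthetic-data generators for every input the pipeline consumes:
# single-cell image stacks of three morphology classes (ramified trees,
# amoeboid blobs, rod-shaped bipolar cells), multi-cell section images,
# open-field trajectories with cosine-modulated body-segment angles, and
# group-structured Cq tables.  Every generator is a pure function of its
# spec: the same spec and seed give bit-identical output, and no global
# RNG state is touched.

#' Cell shape specification
#'
#' Parameters of one synthetic cell.  Class-specific defaults emulate the
#' three morphologies seen around a lesion: `ramified` (branched,
#' soma-centered tree), `amoeboid` (compact blob with a larger body) and
#' `rod` (elongated bipolar cell).
#'
#' @param morph_class `"ramified"`, `"amoeboid"` or `"rod"`.
#' @param soma_radius_um Soma radius (um).  Defaults: ramified 6,
#'   amoeboid 9, rod 6.
#' @param n_primary_processes Number of primary processes.  Defaults:
#'   ramified 5, amoeboid 0, rod 2.
#' @param branch_prob Per-step branching probability of a growing process.
#' @param process_step_um Length of one growth step (um).
#' @param n_steps Number of growth steps per primary process.
#' @param elongation Axis ratio of the soma/body (>= 1).  Defaults:
#'   ramified 1, amoeboid 1.2, rod 4.
#' @param noise_sd Gaussian intensity noise SD (default 5).
#' @param pixel_size_um Pixel size (default 0.8).
#' @param seed Generator seed.
#' @return Validated list of class `cell_shape_spec`.
#' @export
cell_shape_spec <- function(morph_class = c("ramified", "amoeboid", "rod"),
                            soma_radius_um = NULL,
                            n_primary_processes = NULL,
                            branch_prob = NULL,
                            process_step_um = 2,
                            n_steps = NULL,
                            elongation = NULL,
                            noise_sd = 5,
                            pixel_size_um = 0.8,
                            seed = 1) {
  morph_class <- match.arg(morph_class)
  defaults <- switch(morph_class,
    ramified = list(soma = 6, npp = 5, bp = 0.08, steps = 16, elong = 1),
    amoeboid = list(soma = 9, npp = 0, bp = 0, steps = 0, elong = 1.2),
    rod = list(soma = 6, npp = 2, bp = 0.02, steps = 6, elong = 4))
  spec <- list(
    morph_class = morph_class,
    soma_radius_um = soma_radius_um %||% defaults$soma,
    n_primary_processes = n_primary_processes %||% defaults$npp,
    branch_prob = branch_prob %||% defaults$bp,
    process_step_um = process_step_um,
    n_steps = n_steps %||% defaults$steps,
    elongation = elongation %||% defaults$elong,
    noise_sd = noise_sd,
    pixel_size_um = pixel_size_um,
    seed = seed)
  stop_if_not_scalar_pos(spec$soma_radius_um, "soma_radius_um")
  stop_if_not_scalar_pos(spec$pixel_size_um, "pixel_size_um")
  if (spec$branch_prob < 0 || spec$branch_prob > 1) {
    stop("branch_prob must lie in [0, 1]", call. = FALSE)
  }
  if (spec$elongation < 1) stop("elongation must be >= 1", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(spec, class = "cell_shape_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- rasterization helpers --------------------------------------------------

# Mark pixels along a polyline sampled densely; points in (row, col) px.
raster_path <- function(mask, from, to) {
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, ceiling(len / 0.4))
  rr <- round(seq(from[1], to[1], length.out = n))
  cc <- round(seq(from[2], to[2], length.out = n))
  ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  mask[cbind(rr[ok], cc[ok])] <- TRUE
  mask
}

# Elliptical blob with low-order radial wobble, centered in the canvas.
raster_blob <- function(n_px, a_px, b_px, theta, wobble_amp = 0) {
  cc <- (n_px + 1) / 2
  ri <- matrix(seq_len(n_px) - cc, n_px, n_px)
  ci <- t(ri)
  xr <- ci * cos(theta) + ri * sin(theta)
  yr <- -ci * sin(theta) + ri * cos(theta)
  rad <- sqrt((xr / a_px)^2 + (yr / b_px)^2)
  if (wobble_amp > 0) {
    phi <- atan2(yr, xr)
    k <- sample(2:5, 2)
    ps <- stats::runif(2, 0, 2 * pi)
    w <- 1 + wobble_amp * (cos(k[1] * phi + ps[1]) +
                             0.6 * cos(k[2] * phi + ps[2]))
    rad <- rad / pmax(w, 0.5)
  }
  rad <= 1
}

# ---- single-cell generator --------------------------------------------------

#' Generate a synthetic single-cell image stack
#'
#' Draws one cell of the requested morphology class, returning a 3-plane
#' image stack (signal split over z so that the maximum projection
#' recovers the full intensity), the ground-truth binary mask, and the
#' class label.  Ramified trees are grown as recursive random walks
#' rasterized at 1 px and dilated to 2-3 px width, so skeletonization can
#' recover the generative tree; the background is a low-order 2D
#' polynomial plus Gaussian noise, giving the background-correction stage
#' something real to remove.
#'
#' @param spec A [cell_shape_spec].
#' @param canvas_px Optional canvas side length in px; the default is
#'   sized to contain soma and processes (at least 64).  A canvas too
#'   small to contain the soma plus one process step is an error.
#' @param intensity Peak signal intensity (default 200).
#' @param background_amp Amplitude of the polynomial background
#'   (default 25).
#' @return List: `stack` ([image_stack]), `mask` ([cell_mask]),
#'   `morph_class`, `gen_process_length_um` (total generative process
#'   length).
#' @export
make_cell_image <- function(spec, canvas_px = NULL, intensity = 200,
                            background_amp = 25) {
  stopifnot(inherits(spec, "cell_shape_spec"))
  psz <- spec$pixel_size_um
  reach_um <- spec$soma_radius_um * sqrt(spec$elongation) +
    spec$n_steps * spec$process_step_um * 1.15 + 3
  need_px <- 2 * ceiling(reach_um / psz) + 9
  n_px <- canvas_px %||% max(need_px, 64L)
  min_px <- 2 * ceiling((spec$soma_radius_um * sqrt(spec$elongation) +
                           spec$process_step_um) / psz) + 5
  if (n_px < min_px) {
    stop("canvas too small to contain soma and processes", call. = FALSE)
  }
  with_seed(spec$seed, {
    center <- c((n_px + 1) / 2, (n_px + 1) / 2)
    theta <- stats::runif(1, 0, pi)
    a_px <- spec$soma_radius_um * sqrt(spec$elongation) / psz
    b_px <- spec$soma_radius_um / sqrt(spec$elongation) / psz
    wob <- if (spec$morph_class == "amoeboid") 0.05 else 0.02
    soma <- raster_blob(n_px, a_px, b_px, theta, wob)
    proc <- matrix(FALSE, n_px, n_px)
    total_len_um <- 0
    npp <- spec$n_primary_processes
    if (npp > 0 && spec$n_steps > 0) {
      base_dirs <- if (spec$morph_class == "rod") {
        # bipolar: processes leave along the major axis
        theta + c(0, pi)[seq_len(npp) %% 2 + 1]
      } else {
        seq(0, 2 * pi, length.out = npp + 1)[-(npp + 1)] +
          stats::runif(npp, -0.3, 0.3)
      }
      step_px <- spec$process_step_um / psz
      queue <- lapply(seq_len(npp), function(i) {
        list(pos = center, dir = base_dirs[i], left = spec$n_steps,
             depth = 0L, in_soma = TRUE)
      })
      guard <- 0L
      while (length(queue) > 0 && guard < 5000L) {
        guard <- guard + 1L
        el <- queue[[1]]; queue <- queue[-1]
        pos <- el$pos; dir <- el$dir
        for (s in seq_len(el$left)) {
          wiggle <- if (spec$morph_class == "rod") 0.06 else 0.22
          dir <- dir + stats::rnorm(1, 0, wiggle)
          new <- pos + step_px * c(sin(dir), cos(dir))
          if (any(new < 3) || any(new > n_px - 2)) break
          proc <- raster_path(proc, pos, new)
          inside_soma <- sum(((new - center) / c(a_px, b_px))^2) <= 1
          if (!inside_soma) total_len_um <- total_len_um +
              spec$process_step_um
          pos <- new
          if (el$depth < 3 && !inside_soma && s < el$left &&
              stats::runif(1) < spec$branch_prob) {
            queue[[length(queue) + 1L]] <- list(
              pos = pos,
              dir = dir + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1),
              left = ceiling((el$left - s) * 0.7), depth = el$depth + 1L,
              in_soma = FALSE)
          }
        }
      }
      proc <- binary_dilate(proc, 1)
    }
    mask <- soma | proc
    # signal split over 3 z planes; max projection recovers full intensity
    zw <- c(0.65, 1, 0.75)
    u <- matrix(seq(-1, 1, length.out = n_px), n_px, n_px)
    v <- t(u)
    cf <- stats::runif(6, -1, 1)
    bgp <- cf[1] + cf[2] * u + cf[3] * v + cf[4] * u * v +
      cf[5] * u^2 + cf[6] * v^2
    bgp <- (bgp - min(bgp)) / max(diff(range(bgp)), 1e-9) * background_amp
    planes <- lapply(zw, function(w) {
      p <- mask * intensity * w + bgp
      if (spec$noise_sd > 0) {
        p <- p + matrix(stats::rnorm(n_px^2, 0, spec$noise_sd), n_px)
      }
      pmin(pmax(p, 0), 255)
    })
    stack <- image_stack(array(unlist(planes), c(n_px, n_px, 3)), psz)
    list(stack = stack,
         mask = cell_mask(mask, psz, validate = FALSE),
         morph_class = spec$morph_class,
         gen_process_length_um = total_len_um)
  })
}

# ---- multi-cell section -----------------------------------------------------

#' Generate a synthetic multi-cell section
#'
#' Places `n_cells` nonoverlapping cells (rejection sampling on
#' margin-expanded bounding boxes) in a field of the given physical size
#' and returns the section intensity image, ground-truth mask and a
#' centroid/label table.  Per-class counts follow `class_mix` rounded to
#' integers summing to `n_cells`.
#'
#' @param n_cells Number of cells to place.
#' @param class_mix Proportions for (ramified, amoeboid, rod); need not be
#'   normalized.
#' @param field_um Field side length in micrometers (default 500).
#' @param pixel_size_um Pixel size (default 1).
#' @param seed Seed.
#' @param cell_args Extra arguments forwarded to [cell_shape_spec()]
#'   (defaults here shrink cells so dozens pack into the field).
#' @param max_tries Placement attempts per cell before a packing error.
#' @param intensity,background_amp,noise_sd Section image composition.
#' @return List: `image` (matrix), `mask` (logical matrix), `centroids`
#'   (data.frame: `cell`, `morph_class`, `row`, `col`), `pixel_size_um`.
#' @export
make_section <- function(n_cells, class_mix = c(1, 1, 1) / 3,
                         field_um = 500, pixel_size_um = 1, seed = 1,
                         cell_args = list(), max_tries = 200,
                         intensity = 200, background_amp = 20,
                         noise_sd = 4) {
  classes <- c("ramified", "amoeboid", "rod")
  mix <- class_mix / sum(class_mix)
  counts <- diff(round(c(0, cumsum(mix * n_cells))))
  labels <- rep(classes, counts)
  n_px <- round(field_um / pixel_size_um)
  defaults <- list(soma_radius_um = 4, n_steps = 6, process_step_um = 2,
                   noise_sd = 0, pixel_size_um = pixel_size_um)
  with_seed(seed, {
    img_mask <- matrix(FALSE, n_px, n_px)
    boxes <- matrix(0, 0, 4)
    cents <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      args <- utils::modifyList(defaults, cell_args)
      args$morph_class <- labels[i]
      args$soma_radius_um <- if (labels[i] == "amoeboid") {
        args$soma_radius_um * 1.4
      } else {
        args$soma_radius_um
      }
      args$seed <- derive_seed(seed, i)
      cell <- make_cell_image(do.call(cell_shape_spec, args))
      sub <- cell$mask$pixels
      # trim to tight bounding box
      rs <- range(which(rowSums(sub) > 0))
      cs <- range(which(colSums(sub) > 0))
      sub <- sub[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
      h <- nrow(sub); w <- ncol(sub)
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- sample.int(n_px - h - 6, 1) + 3
        c0 <- sample.int(n_px - w - 6, 1) + 3
        box <- c(r0 - 3, r0 + h + 2, c0 - 3, c0 + w + 2)
        clash <- FALSE
        if (nrow(boxes) > 0) {
          clash <- any(boxes[, 1] <= box[2] & boxes[, 2] >= box[1] &
                         boxes[, 3] <= box[4] & boxes[, 4] >= box[3])
        }
        if (!clash) {
          sel <- img_mask[r0:(r0 + h - 1), c0:(c0 + w - 1)]
          img_mask[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- sel | sub
          boxes <- rbind(boxes, box)
          idxs <- which(sub, arr.ind = TRUE)
          cents[[i]] <- data.frame(
            cell = i, morph_class = labels[i],
            row = mean(idxs[, 1]) + r0 - 1,
            col = mean(idxs[, 2]) + c0 - 1)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place cell %d without overlap after %d tries",
                     i, max_tries), call. = FALSE)
      }
    }
    u <- matrix(seq(-1, 1, length.out = n_px), n_px, n_px)
    cf <- stats::runif(6, -1, 1)
    bgp <- cf[1] + cf[2] * u + cf[3] * t(u) + cf[4] * u * t(u) +
      cf[5] * u^2 + cf[6] * t(u)^2
    bgp <- (bgp - min(bgp)) / max(diff(range(bgp)), 1e-9) * background_amp
    img <- img_mask * intensity + bgp
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(n_px^2, 0, noise_sd), n_px)
    }
    list(image = pmin(pmax(img, 0), 255), mask = img_mask,
         centroids = do.call(rbind, cents), pixel_size_um = pixel_size_um)
  })
}

# ---- trajectory generator ---------------------------------------------------

#' Walk specification
#'
#' @param duration_s Recording duration (default 135 s, i.e. 2 min 15 s).
#' @param fps Frame rate (default 30).
#' @param speed_cm_s Walking speed (default 5).
#' @param turn_sd_deg Heading-change SD per sqrt(second) (default 20).
#' @param gait_amplitude_deg Amplitude of the body-segment-angle cosine
#'   (default 12).
#' @param gait_freq_hz Gait frequency (default 2.5; must be below fps/2).
#' @param angle_noise_deg Observation noise SD on the segment angle
#'   (default 0).
#' @param arena_cm Arena side (default 40).
#' @param dropout_rate Per-frame probability of a low-confidence dropout
#'   (default 0.01).
#' @param seed Seed.
#' @return Validated list of class `walk_spec`.
#' @export
walk_spec <- function(duration_s = 135, fps = 30, speed_cm_s = 5,
                      turn_sd_deg = 20, gait_amplitude_deg = 12,
                      gait_freq_hz = 2.5, angle_noise_deg = 0,
                      arena_cm = 40, dropout_rate = 0.01, seed = 1) {
  stop_if_not_scalar_pos(fps, "fps")
  stop_if_not_scalar_pos(arena_cm, "arena_cm")
  if (gait_freq_hz <= 0 || gait_freq_hz >= fps / 2) {
    stop("gait_freq_hz must lie in (0, fps/2)", call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, fps = fps, speed_cm_s = speed_cm_s,
         turn_sd_deg = turn_sd_deg, gait_amplitude_deg = gait_amplitude_deg,
         gait_freq_hz = gait_freq_hz, angle_noise_deg = angle_noise_deg,
         arena_cm = arena_cm, dropout_rate = dropout_rate, seed = seed),
    class = "walk_spec")
}

#' Generate a synthetic open-field trajectory
#'
#' The hip follows a correlated random walk at the specified speed,
#' reflected at the arena walls; the nose-hip-tail-base interior angle
#' follows `offset + A * cos(2*pi*f*t + phi)` plus optional observation
#' noise.  Keypoint confidences are Beta-distributed near 1 with
#' occasional dropouts, so confidence filtering has something to do.
#'
#' @param spec A [walk_spec].
#' @param angle_offset_deg Postural mean of the interior angle
#'   (default 160).
#' @return A [trajectory].
#' @export
make_trajectory <- function(spec, angle_offset_deg = 160) {
  stopifnot(inherits(spec, "walk_spec"))
  with_seed(spec$seed, {
    # n steps cover exactly duration_s of travel (n + 1 positions)
    n <- round(spec$duration_s * spec$fps) + 1L
    dt <- 1 / spec$fps
    cm_per_px <- spec$arena_cm / 400
    nose_len <- 3.5; tail_len <- 3
    margin <- max(nose_len, tail_len) + 1
    heading <- numeric(n)
    heading[1] <- stats::runif(1, 0, 2 * pi)
    if (spec$turn_sd_deg > 0) {
      heading <- heading[1] + cumsum(c(0, stats::rnorm(
        n - 1, 0, spec$turn_sd_deg * sqrt(dt) * pi / 180)))
    } else {
      heading[] <- heading[1]
    }
    hip <- matrix(0, n, 2)
    hip[1, ] <- c(spec$arena_cm / 2, spec$arena_cm / 2)
    for (i in 2:n) {
      stepv <- spec$speed_cm_s * dt * c(cos(heading[i]), sin(heading[i]))
      p <- hip[i - 1, ] + stepv
      for (d in 1:2) { # reflect at padded walls
        if (p[d] < margin) {
          p[d] <- 2 * margin - p[d]
          heading[i:n] <- if (d == 1) pi - heading[i:n] else -heading[i:n]
        } else if (p[d] > spec$arena_cm - margin) {
          p[d] <- 2 * (spec$arena_cm - margin) - p[d]
          heading[i:n] <- if (d == 1) pi - heading[i:n] else -heading[i:n]
        }
      }
      hip[i, ] <- p
    }
    tt <- (seq_len(n) - 1) * dt
    phi <- stats::runif(1, 0, 2 * pi)
    ang <- angle_offset_deg +
      spec$gait_amplitude_deg * cos(2 * pi * spec$gait_freq_hz * tt + phi)
    if (spec$angle_noise_deg > 0) {
      ang <- ang + stats::rnorm(n, 0, spec$angle_noise_deg)
    }
    delta <- (180 - ang) * pi / 180 # nose deflection off the body axis
    nose <- hip + nose_len * cbind(cos(heading + delta),
                                   sin(heading + delta))
    tail <- hip - tail_len * cbind(cos(heading), sin(heading))
    conf <- function() {
      cv <- stats::rbeta(n, 60, 1.5)
      drop <- stats::runif(n) < spec$dropout_rate
      cv[drop] <- stats::runif(sum(drop), 0, 0.5)
      cv
    }
    frames <- data.frame(
      nose_x = nose[, 1] / cm_per_px, nose_y = nose[, 2] / cm_per_px,
      nose_conf = conf(),
      hip_x = hip[, 1] / cm_per_px, hip_y = hip[, 2] / cm_per_px,
      hip_conf = conf(),
      tail_base_x = tail[, 1] / cm_per_px,
      tail_base_y = tail[, 2] / cm_per_px,
      tail_base_conf = conf())
    trajectory(frames, fps = spec$fps, cm_per_px = cm_per_px,
               arena_cm = spec$arena_cm)
  })
}

# ---- Cq table generator -----------------------------------------------------

#' Cq table specification
#'
#' @param n_per_group Samples per group (>= 2).
#' @param genes Gene names, including the reference gene.
#' @param reference_gene Which gene is the internal control (default
#'   `"GAPDH"`).
#' @param group_effect_log2 Named per-gene Cq shift (cycles) applied to
#'   the treated group; a shift of -1 doubles expression.  Unnamed genes
#'   shift by 0.
#' @param cq_sd Replicate noise SD in cycles (default 0.3).
#' @param n_replicates Technical replicates per sample x gene (default 3).
#' @param seed Seed.
#' @return Validated list of class `cq_spec`.
#' @export
cq_spec <- function(n_per_group = 4,
                    genes = c("GAPDH", "iNOS", "IL1b", "IL10"),
                    reference_gene = "GAPDH",
                    group_effect_log2 = c(iNOS = 1),
                    cq_sd = 0.3, n_replicates = 3, seed = 1) {
  if (!reference_gene %in% genes) {
    stop("reference gene must be among `genes`", call. = FALSE)
  }
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (cq_sd < 0) stop("cq_sd must be >= 0", call. = FALSE)
  if (!is.null(names(group_effect_log2)) &&
      reference_gene %in% names(group_effect_log2) &&
      group_effect_log2[[reference_gene]] != 0) {
    stop("the reference gene cannot carry a group effect", call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, genes = genes,
         reference_gene = reference_gene,
         group_effect_log2 = group_effect_log2, cq_sd = cq_sd,
         n_replicates = n_replicates, seed = seed),
    class = "cq_spec")
}

#' Generate a synthetic Cq table
#'
#' Control and treated groups with `n_per_group` samples each; the treated
#' group's target-gene Cq values are shifted by the per-gene effect while
#' the reference gene is unshifted.
#'
#' @param spec A [cq_spec].
#' @return data.frame: `sample`, `group`, `gene`, `replicate`, `cq`.
#' @export
make_cq_table <- function(spec) {
  stopifnot(inherits(spec, "cq_spec"))
  with_seed(spec$seed, {
    base_cq <- stats::setNames(
      ifelse(spec$genes == spec$reference_gene, 20,
             24 + 1.5 * (seq_along(spec$genes) - 1)),
      spec$genes)
    rows <- list()
    for (grp in c("control", "treated")) {
      for (s in seq_len(spec$n_per_group)) {
        sample_id <- sprintf("%s_%02d", grp, s)
        for (g in spec$genes) {
          eff <- if (grp == "treated" && g %in% names(spec$group_effect_log2))
            spec$group_effect_log2[[g]] else 0
          cq <- base_cq[[g]] + eff +
            stats::rnorm(spec$n_replicates, 0, spec$cq_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, group = grp, gene = g,
            replicate = seq_len(spec$n_replicates), cq = cq)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
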