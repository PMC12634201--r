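# Low-level raster operations on images stored as base R matrices
# (rows = y, columns = x, pixel centers at integer coordinates).  These are
# deliberately dependency-light: no image-processing package is assumed,
# only base R, stats and igraph (for connected components and skeleton
# graphs).

# ---- shifting / neighbourhood utilities -------------------------------------

# Shift a numeric/logical matrix by (di, dj), filling vacated cells with
# `fill`.  Positive di moves content down (towards larger row indices).
shift_mat <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- max(1, 1 - di):min(nr, nr - di)
  src_c <- max(1, 1 - dj):min(nc, nc - dj)
  out[src_r + di, src_c + dj] <- m[src_r, src_c]
  out
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= radius^2, , drop = FALSE]
}

# ---- morphology -------------------------------------------------------------

binary_dilate <- function(mask, radius = 1) {
  off <- disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    out <- out | shift_mat(mask, off$di[k], off$dj[k], fill = FALSE)
  }
  out
}

binary_erode <- function(mask, radius = 1) {
  off <- disc_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    out <- out & shift_mat(mask, off$di[k], off$dj[k], fill = FALSE)
  }
  out
}

binary_open <- function(mask, radius = 1) {
  binary_dilate(binary_erode(mask, radius), radius)
}

# ---- connected components ---------------------------------------------------

# Label connected foreground components.  Returns an integer matrix with 0
# for background and 1..k for components (sizes descending is NOT guaranteed;
# labels follow igraph component numbering).
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  id <- integer(nr * nc)
  id[idx] <- seq_along(idx)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  for (s in shifts) {
    r2 <- ri + s[1]; c2 <- ci + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    both <- mask[nb]
    if (any(both)) {
      edges[[length(edges) + 1L]] <- cbind(id[idx[ok][both]], id[nb[both]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  lab[idx] <- as.integer(comp$membership)
  lab
}

n_components <- function(mask, connectivity = 8) {
  max(label_components(mask, connectivity))
}

# ---- separable Gaussian smoothing -------------------------------------------

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Gaussian blur with replicate padding at the borders.
gaussian_blur <- function(img, sigma) {
  stop_if_not_scalar_pos(sigma, "sigma")
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2
  blur1 <- function(m) { # filter along columns
    top <- m[rep(1L, r), , drop = FALSE]
    bot <- m[rep(nrow(m), r), , drop = FALSE]
    p <- rbind(top, m, bot)
    f <- stats::filter(p, k, sides = 2)
    matrix(f[(r + 1):(r + nrow(m)), ], nrow(m), ncol(m))
  }
  t(blur1(t(blur1(img))))
}

# ---- contour extraction -----------------------------------------------------

# Outer contour of the (single largest) foreground region as a subpixel
# marching-squares polygon (via grDevices::contourLines at level 0.5 on the
# zero-padded mask), lightly smoothed with a circular moving average to
# suppress pixel staircase artifacts.  Returns list(x = rows, y = cols).
outer_contour <- function(mask, smooth_window = 3) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- mask * 1
  cl <- grDevices::contourLines(seq_len(nr + 2), seq_len(nc + 2), z, levels = 0.5)
  if (length(cl) == 0L) stop("mask has no contour (empty mask?)", call. = FALSE)
  areas <- vapply(cl, function(cc) polygon_area(cc$x, cc$y), 0)
  c0 <- cl[[which.max(areas)]]
  x <- c0$x - 1; y <- c0$y - 1
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  if (smooth_window > 1 && length(x) >= smooth_window) {
    x <- smooth_closed(x, smooth_window)
    y <- smooth_closed(y, smooth_window)
  }
  list(x = x, y = y)
}

# Circular moving average over a closed sequence of vertices.
smooth_closed <- function(v, w) {
  n <- length(v)
  k <- (w - 1) %/% 2
  vv <- c(v[(n - k + 1):n], v, v[1:k])
  as.numeric(stats::filter(vv, rep(1 / w, w), sides = 2))[(k + 1):(k + n)]
}

# ---- skeletonization (Zhang-Suen thinning) ----------------------------------

# Topology-preserving thinning of a binary mask to a 1-px-wide skeleton.
skeletonize <- function(mask) {
  m <- mask
  m[c(1, nrow(m)), ] <- FALSE
  m[, c(1, ncol(m))] <- FALSE
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, 1, 0, FALSE);  p3 <- shift_mat(m, 1, -1, FALSE)
      p4 <- shift_mat(m, 0, -1, FALSE); p5 <- shift_mat(m, -1, -1, FALSE)
      p6 <- shift_mat(m, -1, 0, FALSE); p7 <- shift_mat(m, -1, 1, FALSE)
      p8 <- shift_mat(m, 0, 1, FALSE);  p9 <- shift_mat(m, 1, 1, FALSE)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# ---- skeleton graph ---------------------------------------------------------

# Build an igraph of 8-connected skeleton pixels, edge weights 1 for
# axis-aligned steps and sqrt(2) for diagonals.  Where a diagonal shortcut
# coexists with its two axis-aligned legs, the diagonal is dropped so path
# lengths are not double counted.
skeleton_graph <- function(skel) {
  nr <- nrow(skel)
  idx <- which(skel)
  if (length(idx) == 0L) {
    return(list(graph = igraph::make_empty_graph(0, directed = FALSE),
                coords = matrix(0, 0, 2)))
  }
  id <- integer(nr * ncol(skel))
  id[idx] <- seq_along(idx)
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  edge_for <- function(di, dj) {
    r2 <- ri + di; c2 <- ci + dj
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(skel)
    nb <- (c2 - 1L) * nr + r2
    ok[ok] <- skel[nb[ok]]
    list(from = idx[ok], to = nb[ok])
  }
  ax <- list(edge_for(1L, 0L), edge_for(0L, 1L))
  di <- list(edge_for(1L, 1L), edge_for(1L, -1L))
  # drop a diagonal (a)-(d) whenever a 4-connected leg pixel bridges the
  # same corner: connectivity survives through the leg, and without the
  # shortcut edge right-angle bends stay simple paths instead of spawning
  # triangle junctions
  keep_diag <- function(e) {
    if (length(e$from) == 0L) return(e)
    fr <- ((e$from - 1L) %% nr) + 1L; fc <- ((e$from - 1L) %/% nr) + 1L
    tr <- ((e$to - 1L) %% nr) + 1L;   tc <- ((e$to - 1L) %/% nr) + 1L
    leg1 <- skel[cbind(fr, tc)]
    leg2 <- skel[cbind(tr, fc)]
    drop <- leg1 | leg2
    list(from = e$from[!drop], to = e$to[!drop])
  }
  di <- lapply(di, keep_diag)
  from <- c(ax[[1]]$from, ax[[2]]$from, di[[1]]$from, di[[2]]$from)
  to <- c(ax[[1]]$to, ax[[2]]$to, di[[1]]$to, di[[2]]$to)
  w <- c(rep(1, length(ax[[1]]$from) + length(ax[[2]]$from)),
         rep(sqrt(2), length(di[[1]]$from) + length(di[[2]]$from)))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from) > 0) {
    g <- igraph::add_edges(g, rbind(id[from], id[to]), weight = w)
  }
  list(graph = g, coords = cbind(row = ri, col = ci))
}

# Remove terminal spur branches shorter than `min_len_px` from a skeleton,
# iterating so that branches separated by a pruned spur's junction re-merge
# into one path.  The longest branch is never pruned.
prune_spurs <- function(skel, min_len_px, max_iter = 5) {
  for (it in seq_len(max_iter)) {
    sg <- skeleton_graph(skel)
    br <- skeleton_branches(sg, with_members = TRUE)
    if (nrow(br) == 0L) return(skel)
    members <- attr(br, "members")
    spur <- br$terminal & br$length < min_len_px
    spur[which.max(br$length)] <- FALSE
    if (!any(spur)) return(skel)
    for (k in which(spur)) {
      px <- sg$coords[members[[k]], , drop = FALSE]
      skel[px] <- FALSE
    }
  }
  skel
}

# Decompose a skeleton graph into branches: maximal paths between nodes of
# degree != 2 (endpoints and junctions).  Returns a data.frame with one row
# per branch: path length (weighted), Euclidean end-to-end distance between
# the branch terminals, and whether the branch has a free endpoint (a
# degree-1 tip of the skeleton, as opposed to running between junctions).
# With `with_members = TRUE` the per-branch vertex indices (junctions
# excluded) are attached as attribute "members".
skeleton_branches <- function(sg, with_members = FALSE) {
  empty <- data.frame(length = numeric(0), euclid = numeric(0),
                      terminal = logical(0))
  g <- sg$graph
  coords <- sg$coords
  n <- igraph::vcount(g)
  if (n == 0L) return(empty)
  deg <- igraph::degree(g)
  junction <- deg >= 3
  core <- which(!junction)
  if (length(core) == 0L) return(empty)
  sub <- igraph::induced_subgraph(g, core)
  comp <- igraph::components(sub)
  w_all <- igraph::E(g)$weight
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  in_core <- !junction
  branches <- vector("list", comp$no)
  member_list <- vector("list", comp$no)
  for (k in seq_len(comp$no)) {
    members <- core[comp$membership == k]
    in_comp <- logical(n); in_comp[members] <- TRUE
    # edges internal to the component plus edges linking it to junctions
    e_int <- in_comp[ends[, 1]] & in_comp[ends[, 2]]
    e_link <- xor(in_comp[ends[, 1]], in_comp[ends[, 2]]) &
      !(in_core[ends[, 1]] & in_core[ends[, 2]])
    len <- sum(w_all[e_int]) + sum(w_all[e_link])
    if (len == 0) next # isolated single pixel
    member_list[[k]] <- members
    link_junc <- unique(as.vector(ends[e_link, , drop = FALSE]))
    link_junc <- link_junc[junction[link_junc]]
    # terminals: degree within the branch (internal + link edges) equal to 1
    vs <- c(members, link_junc)
    deg_branch <- integer(n)
    cnt_int <- tabulate(as.vector(ends[e_int, , drop = FALSE]), nbins = n)
    cnt_lnk <- tabulate(as.vector(ends[e_link, , drop = FALSE]), nbins = n)
    deg_branch <- cnt_int + cnt_lnk
    term_vs <- vs[deg_branch[vs] == 1]
    has_tip <- any(deg[members] <= 1)
    if (length(term_vs) < 2) {
      # cycle (or lollipop fragment): straightness undefined for it
      branches[[k]] <- data.frame(length = len, euclid = NA_real_,
                                  terminal = has_tip)
      next
    }
    pr <- coords[term_vs, , drop = FALSE]
    eu <- max(stats::dist(pr))
    branches[[k]] <- data.frame(length = len, euclid = eu, terminal = has_tip)
  }
  keep <- !vapply(branches, is.null, TRUE)
  out <- do.call(rbind, branches[keep])
  if (is.null(out)) out <- empty
  if (with_members) attr(out, "members") <- member_list[keep]
  out
}

# Count skeleton endpoints (degree-1 pixels).
skeleton_endpoints <- function(skel) {
  sg <- skeleton_graph(skel)
  if (igraph::vcount(sg$graph) == 0L) return(0L)
  sum(igraph::degree(sg$graph) == 1)
}
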