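# Geometric fixtures and independent brute-force oracles used across the
# suite.  All fixtures are built in code; no binary data ships with the
# package.

disc_mask <- function(r, n = 2 * r + 11) {
  cc <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
}

square_mask <- function(side, pad = 10) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

bar_mask <- function(len, thick = 3, pad = 10) {
  m <- matrix(FALSE, thick + 2 * pad, len + 2 * pad)
  m[pad + seq_len(thick), pad + seq_len(len)] <- TRUE
  m
}

# Right-angle L: two legs of pixel length a and b, `thick` px wide.
l_mask <- function(a, b, thick = 3, pad = 10) {
  n <- max(a, b) + 2 * pad + thick
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(a), pad + seq_len(thick)] <- TRUE
  m[pad + a - seq_len(thick) + 1, pad + seq_len(b)] <- TRUE
  m
}

# Plus sign: four straight arms of length `arm` around a small center.
plus_mask <- function(arm = 40, thick = 3, pad = 8) {
  n <- 2 * arm + thick + 2 * pad
  c0 <- pad + arm
  m <- matrix(FALSE, n, n)
  m[c0 + seq_len(thick), (pad + 1):(n - pad)] <- TRUE
  m[(pad + 1):(n - pad), c0 + seq_len(thick)] <- TRUE
  m
}

# Sierpinski carpet of the given level, rasterized at `px` pixels per
# smallest cell.
carpet_mask <- function(level = 4, px = 3) {
  n <- 3^level
  keep <- function(i, j) {
    l <- level
    while (l > 0) {
      if (i %% 3 == 1 && j %% 3 == 1) return(FALSE)
      i <- i %/% 3; j <- j %/% 3; l <- l - 1
    }
    TRUE
  }
  m <- outer(0:(n - 1), 0:(n - 1), Vectorize(keep))
  m[rep(seq_len(n), each = px), rep(seq_len(n), each = px)]
}

# ---- independent oracles ----------------------------------------------------

# Gliding-box lacunarity by explicit double loop (population variance),
# one value per box size.
lacunarity_brute <- function(mask, sizes) {
  vapply(sizes, function(s) {
    nr <- nrow(mask) - s + 1
    nc <- ncol(mask) - s + 1
    masses <- numeric(nr * nc)
    k <- 0
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        k <- k + 1
        masses[k] <- sum(mask[i:(i + s - 1), j:(j + s - 1)])
      }
    }
    mu <- mean(masses)
    mean((masses - mu)^2) / mu^2 + 1
  }, 0)
}

# Otsu threshold by exhaustive search over the same 256-bin histogram.
otsu_brute <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  best <- -Inf; best_t <- NA
  for (t in seq_len(n_bins - 1)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):n_bins] * mids[(t + 1):n_bins]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_t <- breaks[t + 1] }
  }
  best_t
}

# Mean silhouette width by the O(n^2) textbook formula.
silhouette_brute <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l) {
      mean(d[i, labels == l])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Generate a matched batch of profiled synthetic cells (used by classify /
# acceptance tests).
profile_batch <- function(class, n, seed_offset = 0) {
  profs <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- make_cell_image(cell_shape_spec(class, seed = i + seed_offset))
    profs[[i]] <- morphometric_profile(cell$mask)
  }
  do.call(rbind, profs)
}
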