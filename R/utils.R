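# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All generators route their randomness
# through this so that no call leaks global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483629
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive scalar", name), call. = FALSE)
  }
  invisible(x)
}

#' Polygon area by the Shoelace formula
#'
#' Area of a simple polygon from its vertex coordinates, computed as half the
#' absolute sum of signed cross-products of consecutive vertices.  Vertices
#' may be given in either winding order; the polygon is closed implicitly.
#'
#' @param x,y Numeric vectors of vertex coordinates (equal length, >= 3).
#' @return Area in squared coordinate units.
#' @examples
#' polygon_area(c(0, 4, 4, 0), c(0, 0, 3, 3)) # 12
#' @export
polygon_area <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("polygon needs >= 3 vertices with matching x/y", call. = FALSE)
  }
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Perimeter of a closed polygon (first vertex is implicitly repeated).
polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' invariant to label permutation.  1 = identical partitions, ~0 = chance.
#'
#' @param a,b Vectors of cluster labels (any atomic type, equal length).
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
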