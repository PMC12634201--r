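# Unsupervised structure discovery: Ward hierarchical clustering on
# MMI-selected features with silhouette-based selection of the number of
# clusters, and a PCA embedding for visualization.

#' Select features by MMI threshold
#'
#' Features whose multimodality index meets the threshold are retained for
#' clustering (order-stable).
#'
#' @param mmi_table MMI table (see [mmi_reference()]).
#' @param threshold MMI cutoff (default 0.5).
#' @return Character vector of feature names.
#' @export
select_features <- function(mmi_table = mmi_reference(), threshold = 0.5) {
  validate_mmi_table(mmi_table)
  out <- mmi_table$feature[mmi_table$mmi >= threshold]
  if (length(out) == 0L) {
    stop(sprintf("no features with MMI >= %g", threshold), call. = FALSE)
  }
  out
}

#' Mean silhouette width of a labeling
#'
#' @param d A `dist` object (or distance matrix).
#' @param labels Integer/factor cluster labels.
#' @return Mean silhouette width over all points.
#' @export
silhouette_score <- function(d, labels) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, "sil_width"])
}

#' Ward hierarchical clustering with silhouette-selected k
#'
#' Agglomerative clustering under the Ward objective on Euclidean
#' distances.  The tree is cut at every `k` in `k_range`; the final
#' labeling is the cut maximizing the mean silhouette width.
#'
#' @param features Numeric matrix or data.frame of per-cell feature values
#'   (rows = cells).
#' @param k_range Candidate cluster numbers (default `2:8`).
#' @param scale How to normalize columns first: `"zscore"` (default),
#'   `"minmax"`, or `"none"`.
#' @return List of class `cluster_result`: `labels`, `k`, `hclust`,
#'   `silhouette_by_k` (named numeric), `features_used`.
#' @export
cluster_cells <- function(features, k_range = 2:8,
                          scale = c("zscore", "minmax", "none")) {
  scale <- match.arg(scale)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  x <- normalize_columns(x, scale)
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    silhouette_score(d, stats::cutree(hc, k))
  }, 0)
  names(sil) <- k_range
  k_best <- k_range[which.max(sil)]
  structure(
    list(labels = stats::cutree(hc, k_best), k = k_best, hclust = hc,
         silhouette_by_k = sil,
         features_used = colnames(features)),
    class = "cluster_result")
}

normalize_columns <- function(x, scale) {
  if (scale == "zscore") {
    s <- apply(x, 2, stats::sd)
    if (any(s == 0)) stop("constant feature column", call. = FALSE)
    x <- base::scale(x)
  } else if (scale == "minmax") {
    rng <- apply(x, 2, range)
    span <- rng[2, ] - rng[1, ]
    if (any(span == 0)) stop("constant feature column", call. = FALSE)
    x <- sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
  }
  x
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d (silhouette %.3f), n = %d cells\n",
              x$k, max(x$silhouette_by_k), length(x$labels)))
  invisible(x)
}

#' PCA embedding of morphometric features
#'
#' Centered principal component analysis.  Loadings follow a reproducible
#' sign convention (largest-magnitude loading positive per component).  A
#' warning is raised when the first two components explain less than 70%
#' of the variance -- the adequacy bar used for 2D morphology maps.
#'
#' @param features Numeric matrix or data.frame (rows = cells).
#' @param n_components Number of components to return (default 2).
#' @param scale Column normalization before PCA: `"zscore"` (default),
#'   `"minmax"`, or `"none"`.
#' @return List of class `pca_result`: `scores`, `loadings`,
#'   `explained_variance_ratio` (full spectrum), `center`.
#' @export
pca_embed <- function(features, n_components = 2,
                      scale = c("zscore", "minmax", "none")) {
  scale <- match.arg(scale)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("PCA needs >= 2 cells and >= 2 features", call. = FALSE)
  }
  x <- normalize_columns(x, scale)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (all(pc$sdev == 0)) stop("degenerate (rank-0) data", call. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  nc <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(nc), drop = FALSE]
  sco <- pc$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) { # sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  if (sum(ratio[1:min(2, length(ratio))]) < 0.70) {
    warning("first two principal components explain < 70% of the variance",
            call. = FALSE)
  }
  structure(
    list(scores = sco, loadings = rot, explained_variance_ratio = ratio,
         center = pc$center),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  r <- x$explained_variance_ratio
  cat(sprintf("<pca_result> %d components; PC1+PC2 explain %.1f%%\n",
              ncol(x$scores), 100 * sum(r[1:min(2, length(r))])))
  invisible(x)
}

#' Cluster centroids in PC space
#'
#' Mean PC coordinates per group, for annotating 2D morphology maps.
#'
#' @param pca A `pca_result`.
#' @param groups Grouping vector (cluster labels or conditions).
#' @return data.frame of per-group centroid coordinates.
#' @export
pc_centroids <- function(pca, groups) {
  sco <- as.data.frame(pca$scores)
  agg <- stats::aggregate(sco, by = list(group = groups), FUN = mean)
  agg
}
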