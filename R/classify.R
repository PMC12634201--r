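# Amoeboid/ramified classification.  Each of the 16 morphometric features
# carries a multimodality index (MMI) -- a bimodality statistic of its
# distribution across cells -- and a direction label saying which morphology
# larger values indicate.  Min-max-scaled features are combined into an
# amoeboid index and a ramified index; a cell is assigned the type with the
# larger index, and the per-sample percentage of amoeboid-classified cells
# is the "amoeboid ratio".

#' Multimodality index (bimodality coefficient)
#'
#' Sarle-type bimodality coefficient of one feature across cells:
#' `b = (g1^2 + 1) / (g2 + 3(n-1)^2 / ((n-2)(n-3)))`, with `g1` the sample
#' skewness and `g2` the sample excess kurtosis (moment estimators).
#' Unimodal symmetric distributions sit low (normal: 1/3, uniform: 5/9);
#' a balanced two-point mixture approaches the maximum of 1.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @return Scalar in (0, 1] for non-degenerate samples.
#' @export
compute_mmi <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4) stop("MMI needs at least 4 finite values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("MMI undefined for zero-variance feature", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Reference MMI table
#'
#' MMI values and direction labels for the 16 morphometric features, as
#' determined on the original injured-cortex microglia population.  Five
#' features point in the amoeboid direction and eleven in the ramified
#' direction.  Use this fixed table to reproduce the published weighting,
#' or [mmi_from_data()] to re-derive weights from a new dataset.
#'
#' @return data.frame with columns `feature`, `mmi`, `direction`.
#' @export
mmi_reference <- function() {
  path <- system.file("extdata", "mmi_reference.csv", package = "mgmorph")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mmi_table(tab)
  tab
}

#' Compute an MMI table from data
#'
#' Derives per-feature MMI values from the profiles at hand and assigns
#' each feature the direction label of the reference table.
#'
#' @param profiles data.frame of morphometric profiles (16 feature
#'   columns).
#' @param directions Optional data.frame mapping `feature` to `direction`;
#'   defaults to the reference table's directions.
#' @return data.frame with columns `feature`, `mmi`, `direction`.
#' @export
mmi_from_data <- function(profiles, directions = NULL) {
  if (is.null(directions)) directions <- mmi_reference()[, c("feature", "direction")]
  feats <- intersect(morph_features(), names(profiles))
  mmi <- vapply(feats, function(f) compute_mmi(profiles[[f]]), 0)
  out <- data.frame(feature = feats, mmi = unname(mmi),
                    stringsAsFactors = FALSE)
  merge(out, directions, by = "feature", sort = FALSE)
}

validate_mmi_table <- function(tab) {
  stopifnot(all(c("feature", "mmi", "direction") %in% names(tab)))
  if (anyDuplicated(tab$feature)) {
    stop("duplicate feature names in MMI table", call. = FALSE)
  }
  if (any(tab$mmi < 0 | tab$mmi > 1)) {
    stop("MMI values must lie in [0, 1]", call. = FALSE)
  }
  if (!all(tab$direction %in% c("amoeboid", "ramified"))) {
    stop("direction must be 'amoeboid' or 'ramified'", call. = FALSE)
  }
  invisible(tab)
}

#' Min-max feature scaling
#'
#' Scales each feature column to `[0, 1]` across the analyzed population
#' (minimum to 0, maximum to 1).  Constant columns are dropped with a
#' warning.  Non-feature columns (`cell`, `sample`, ...) are passed
#' through unchanged.
#'
#' @param profiles data.frame with the morphometric feature columns.
#' @return data.frame of the same shape with scaled feature columns.
#' @export
scale_features <- function(profiles) {
  if (nrow(profiles) < 2) stop("need >= 2 cells to scale", call. = FALSE)
  feats <- intersect(morph_features(), names(profiles))
  dropped <- character(0)
  for (f in feats) {
    v <- profiles[[f]]
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(diff(rng)) || diff(rng) == 0) {
      dropped <- c(dropped, f)
      profiles[[f]] <- NULL
    } else {
      profiles[[f]] <- (v - rng[1]) / diff(rng)
    }
  }
  if (length(dropped)) {
    warning("dropped constant feature(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  profiles
}

#' Amoeboid and ramified indices
#'
#' Combines min-max-scaled features into one index per direction.  By
#' default each index is the MMI-weighted mean of the scaled features whose
#' direction matches (weights = MMI values), so indices built from 5 and 11
#' features live on a common `[0, 1]` scale; `method = "sum"` restores
#' plain weighted sums.
#'
#' @param scaled data.frame of scaled profiles (see [scale_features()]).
#' @param mmi_table MMI table (default [mmi_reference()]).
#' @param method `"weighted_mean"` (default) or `"sum"`.
#' @return data.frame with columns `amoeboid_index`, `ramified_index`
#'   (plus any non-feature columns of the input).
#' @export
morphology_indices <- function(scaled, mmi_table = mmi_reference(),
                               method = c("weighted_mean", "sum")) {
  method <- match.arg(method)
  validate_mmi_table(mmi_table)
  index_for <- function(dir) {
    tab <- mmi_table[mmi_table$direction == dir, , drop = FALSE]
    missing <- setdiff(tab$feature, names(scaled))
    if (length(missing)) {
      stop("missing feature column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    mat <- as.matrix(scaled[, tab$feature, drop = FALSE])
    w <- tab$mmi
    if (method == "weighted_mean") {
      as.numeric(mat %*% w) / sum(w)
    } else {
      as.numeric(mat %*% w)
    }
  }
  keep <- setdiff(names(scaled), morph_features())
  out <- scaled[, keep, drop = FALSE]
  out$amoeboid_index <- index_for("amoeboid")
  out$ramified_index <- index_for("ramified")
  out
}

#' Classify cells as amoeboid or ramified
#'
#' A cell is labeled `amoeboid` iff its amoeboid index strictly exceeds its
#' ramified index; ties go to `ramified` (the conservative choice when
#' asking whether a treatment reduces amoeboid counts).
#'
#' @param indices data.frame with `amoeboid_index` and `ramified_index`
#'   columns (see [morphology_indices()]).
#' @return The input with an added factor column `label`.
#' @export
classify_cells <- function(indices) {
  stopifnot(all(c("amoeboid_index", "ramified_index") %in% names(indices)))
  if (any(!is.finite(indices$amoeboid_index)) ||
      any(!is.finite(indices$ramified_index))) {
    stop("indices must be finite", call. = FALSE)
  }
  indices$label <- factor(
    ifelse(indices$amoeboid_index > indices$ramified_index,
           "amoeboid", "ramified"),
    levels = c("amoeboid", "ramified"))
  indices
}

#' Per-sample amoeboid ratio
#'
#' Percentage of cells per sample whose amoeboid index exceeds their
#' ramified index, i.e. 100 x (amoeboid count) / (total count).
#'
#' @param classifications data.frame with columns `sample` and `label`
#'   (see [classify_cells()]).
#' @return data.frame with columns `sample`, `n_cells`, `amoeboid_ratio`.
#' @export
amoeboid_ratio <- function(classifications) {
  stopifnot(all(c("sample", "label") %in% names(classifications)))
  keep <- !is.na(classifications$label)
  cls <- classifications[keep, , drop = FALSE]
  if (nrow(cls) == 0L) {
    warning("no classified cells", call. = FALSE)
    return(data.frame(sample = character(0), n_cells = integer(0),
                      amoeboid_ratio = numeric(0)))
  }
  agg <- stats::aggregate(
    list(n_cells = cls$label),
    by = list(sample = cls$sample),
    FUN = length)
  amo <- stats::aggregate(
    list(amoeboid_ratio = cls$label == "amoeboid"),
    by = list(sample = cls$sample),
    FUN = function(x) 100 * mean(x))
  merge(agg, amo, by = "sample", sort = TRUE)
}

#' End-to-end classification of a profile table
#'
#' Convenience wrapper: scale, build indices, classify.
#'
#' @inheritParams morphology_indices
#' @param profiles Raw (unscaled) morphometric profiles.
#' @return data.frame with indices and `label`.
#' @export
classify_profiles <- function(profiles, mmi_table = mmi_reference(),
                              method = "weighted_mean") {
  classify_cells(morphology_indices(scale_features(profiles),
                                    mmi_table = mmi_table,
                                    method = method))
}
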