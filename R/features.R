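#' Handcrafted statistical features of a window set
#'
#' Computes, separately for every channel, the seven window statistics
#' used throughout the package: mean, variance, standard deviation,
#' median, max, min and interquartile range.  The variance is the
#' population form `(1/W) * sum((r - mean)^2)` and the standard deviation
#' its square root.  Quartiles use linear interpolation between order
#' statistics (R's default quantile type 7), so `iqr = Q3 - Q1` under
#' that convention.  The output is channel-major: all seven statistics of
#' channel 0, then channel 1, and so on, giving exactly `7 * C` values
#' per window.
#'
#' @param windows a `sensor_windows` container (or a single `W x C`
#'   matrix, in which case a bare feature vector is returned)
#' @return a `feature_set`: list with `X` (`N x 7C` matrix with named
#'   columns `ch{j}_{stat}`), `activity`, `person`, `t`
#' @export
extract_features <- function(windows) {
  stat_names <- c("mean", "var", "std", "median", "max", "min", "iqr")
  feat1 <- function(v) {
    m <- mean(v)
    va <- mean((v - m)^2)
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    c(m, va, sqrt(va), stats::median(v), max(v), min(v), q[2] - q[1])
  }
  if (is.matrix(windows)) {
    if (nrow(windows) < 1) stop("empty window")
    out <- as.vector(apply(windows, 2, feat1))
    names(out) <- paste0("ch", rep(seq_len(ncol(windows)) - 1, each = 7),
                         "_", rep(stat_names, ncol(windows)))
    return(out)
  }
  stopifnot(inherits(windows, "sensor_windows"))
  n <- n_windows(windows)
  if (n < 1 || windows$W < 1) stop("empty window set")
  C <- windows$n_channels
  X <- matrix(0, n, 7 * C)
  for (i in seq_len(n)) {
    X[i, ] <- as.vector(apply(matrix(windows$values[i, , ], windows$W, C),
                              2, feat1))
  }
  colnames(X) <- paste0("ch", rep(seq_len(C) - 1, each = 7), "_",
                        rep(stat_names, C))
  structure(list(X = X, activity = windows$activity,
                 person = windows$person, t = windows$t),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d samples x %d features (%d channels x 7 stats)\n",
              nrow(x$X), ncol(x$X), ncol(x$X) / 7))
  invisible(x)
}

#' Temporal neighborhood of a window ordinal
#'
#' Returns the ordinals `{t - radius, ..., t + radius}` clipped to
#' `[0, n_windows)`.  The center `t` is included; near a stream boundary
#' the set simply shrinks.  Ordinals are 0-based, matching the `t` slot
#' of `sensor_windows`.
#'
#' @param t 0-based window ordinal
#' @param n_windows number of windows in the stream, > 0
#' @param radius half-width of the neighborhood (default 2 gives the
#'   five windows centered on `t`)
#' @return integer vector of ordinals, ascending
#' @export
temporal_neighborhood <- function(t, n_windows, radius = 2) {
  if (n_windows <= 0) stop("n_windows must be positive")
  stopifnot(t >= 0, t < n_windows, radius >= 0)
  lo <- max(0, t - radius)
  hi <- min(n_windows - 1, t + radius)
  as.integer(lo:hi)
}

#' k-nearest neighbors in handcrafted-feature space
#'
#' Euclidean distances in (optionally per-feature z-scored) feature
#' space.  The query point itself is excluded from its neighbor set;
#' ties are broken toward the lower index, so the result is
#' deterministic.
#'
#' @param features a `feature_set`, or a numeric matrix of feature rows
#' @param k neighbors per sample (default 5)
#' @param standardize z-score each feature column first (default TRUE;
#'   columns with zero spread are left unscaled)
#' @return list of integer vectors: element `i` holds the 1-based row
#'   indices of the `k` nearest samples to row `i`
#' @export
feature_knn <- function(features, k = 5, standardize = TRUE) {
  X <- if (inherits(features, "feature_set")) features$X else as.matrix(features)
  n <- nrow(X)
  if (n <= k)
    stop("need more than k = ", k, " samples for kNN; lower k")
  if (standardize) X <- standardize_cols(X)$X
  # all-pairs squared distances via the Gram expansion
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  lapply(seq_len(n), function(i) {
    d <- D2[i, ]
    d[i] <- Inf
    # order() is stable: equal distances resolve to the lower index
    as.integer(order(d)[seq_len(k)])
  })
}

# z-score columns; zero-spread columns pass through unscaled.
standardize_cols <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale < 1e-12] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Build the temporal and feature-space neighborhood index
#'
#' Temporal neighborhoods are computed within each person's window
#' sequence (temporal continuity is a per-stream property); feature-space
#' kNN is computed across the whole set (cross-person commonality is the
#' point of feature consistency).  Both are returned as 1-based row
#' indices into the feature matrix, ready for the consistency losses.
#'
#' @param features a `feature_set`
#' @param radius temporal half-width (default 2)
#' @param k feature-space neighbors (default 5)
#' @param standardize z-score features before the kNN search
#' @return a `neighborhood_index`: list with `temporal` and `feature`
#'   (lists of integer index vectors), plus `radius` and `k`
#' @export
build_neighborhoods <- function(features, radius = 2, k = 5,
                                standardize = TRUE) {
  stopifnot(inherits(features, "feature_set"))
  n <- nrow(features$X)
  temporal <- vector("list", n)
  for (p in unique(features$person)) {
    rows <- which(features$person == p)
    rows <- rows[order(features$t[rows])]
    np <- length(rows)
    for (j in seq_len(np)) {
      nb <- temporal_neighborhood(j - 1L, np, radius)
      temporal[[rows[j]]] <- rows[nb + 1L]
    }
  }
  structure(list(temporal = temporal,
                 feature = feature_knn(features, k, standardize),
                 radius = radius, k = k),
            class = "neighborhood_index")
}

#' @export
print.neighborhood_index <- function(x, ...) {
  cat(sprintf("neighborhood_index: %d samples, temporal radius %d, feature k = %d\n",
              length(x$temporal), x$radius, x$k))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' Layout: `person,activity,t,feat_0..feat_{7C-1}`; a sidecar file
#' `<path>.names` lists the feature names `ch{j}_{stat}` one per line.
#' @param features a `feature_set`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(person = features$person, activity = features$activity,
                   t = features$t)
  X <- features$X
  for (j in seq_len(ncol(X))) df[[paste0("feat_", j - 1)]] <- X[, j]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  writeLines(colnames(X), paste0(path, ".names"))
  invisible(path)
}

#' Read a feature table written by [write_features_csv()]
#' @param path CSV path
#' @return a `feature_set`
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  fcols <- grep("^feat_[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("feat_", "", fcols)))]
  X <- as.matrix(df[, fcols, drop = FALSE])
  names_file <- paste0(path, ".names")
  if (file.exists(names_file)) colnames(X) <- readLines(names_file)
  structure(list(X = X, activity = df$activity, person = df$person,
                 t = df$t),
            class = "feature_set")
}
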