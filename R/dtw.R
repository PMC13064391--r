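#' Dynamic time warping distance between two feature series
#'
#' Classic DTW on two multivariate series: local cost is the Euclidean
#' distance between feature vectors, and the returned value is the minimal
#' cumulative cost over monotone, continuity-constrained warping paths
#' (steps advance one element in either or both series). By default the
#' cumulative cost is not normalized by path length; `normalize = TRUE`
#' divides by the length of the optimal path's cost count proxy
#' `n + m` (series lengths), a common normalization when comparing series
#' of very different durations.
#'
#' DTW as used here is a premetric: non-negative, zero on identical series
#' and symmetric, but it does not satisfy the triangle inequality.
#'
#' @param a,b Numeric matrices (rows = time, columns = features) with the
#'   same number of columns, or numeric vectors (treated as 1-column).
#' @param normalize Divide the cumulative cost by `nrow(a) + nrow(b)`.
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))
dtw_distance <- function(a, b, normalize = FALSE) {
  a <- as_series_matrix(a)
  b <- as_series_matrix(b)
  if (ncol(a) != ncol(b)) {
    stop("series have different feature dimensionality", call. = FALSE)
  }
  if (nrow(a) == 0 || nrow(b) == 0) stop("series must be non-empty", call. = FALSE)
  d <- .dtw_cpp(a, b)
  if (normalize) d <- d / (nrow(a) + nrow(b))
  d
}

as_series_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    x
  } else {
    matrix(as.numeric(x), ncol = 1)
  }
}

#' DTW cross-distance matrix of a cohort
#'
#' Computes the symmetric matrix of pairwise DTW distances between the
#' standardized feature series of all tracks, each unordered pair once.
#'
#' @param fs A `"feature_series_set"` from [build_feature_series()], or a
#'   plain list of series matrices.
#' @param normalize Passed to [dtw_distance()].
#' @return Symmetric numeric matrix with zero diagonal; dimnames are the
#'   track ids when available.
#' @export
cross_distance_matrix <- function(fs, normalize = FALSE) {
  series <- if (inherits(fs, "feature_series_set")) fs$series else fs
  if (length(series) < 2) stop("need at least 2 series", call. = FALSE)
  series <- lapply(series, as_series_matrix)
  D <- .dtw_cross_cpp(series)
  if (normalize) {
    lens <- vapply(series, nrow, integer(1))
    D <- D / outer(lens, lens, `+`)
    diag(D) <- 0
  }
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite DTW distance for pair (%d, %d)", bad[1], bad[2]),
      call. = FALSE
    )
  }
  if (inherits(fs, "feature_series_set")) {
    dimnames(D) <- list(fs$track_ids, fs$track_ids)
  }
  D
}
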