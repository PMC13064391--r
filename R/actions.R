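#' 2-D UMAP embedding of a precomputed distance matrix
#'
#' Embeds the DTW cross-distance matrix into two dimensions with UMAP in
#' precomputed-distance mode. Runs single-threaded with deterministic
#' stochastic-gradient descent so that a fixed seed reproduces the
#' embedding exactly.
#'
#' @param D Symmetric distance matrix (e.g. from
#'   [cross_distance_matrix()]).
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (default 15); must be < n.
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @return n x 2 numeric matrix; rownames carried over from `D`.
#' @export
embed_2d <- function(D, seed = 1L, n_neighbors = 15L, min_dist = 0.1) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < n_neighbors + 1) {
    stop(sprintf(
      "n = %d is too small for n_neighbors = %d; lower n_neighbors to at most %d",
      n, n_neighbors, n - 1
    ), call. = FALSE)
  }
  emb <- with_seed(seed, {
    uwot::umap(
      stats::as.dist(D),
      n_neighbors = n_neighbors, min_dist = min_dist,
      n_threads = 1, n_sgd_threads = 0, batch = FALSE
    )
  })
  rownames(emb) <- rownames(D)
  colnames(emb) <- c("u1", "u2")
  emb
}

#' k-means clustering of the embedding
#'
#' Partitions the 2-D embedding into `k` clusters (default 5, matching the
#' five behavioral actions) with seeded multi-restart k-means.
#'
#' @param embedding n x 2 matrix from [embed_2d()].
#' @param k Number of clusters (default 5).
#' @param seed Integer seed.
#' @param n_init Number of random restarts (default 10).
#' @return Integer vector of 0-based cluster ids, named by the embedding's
#'   rownames.
#' @export
cluster_tracks <- function(embedding, k = 5L, seed = 1L, n_init = 10L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < k) stop(sprintf("n = %d tracks < k = %d clusters", n, k), call. = FALSE)
  km <- with_seed(seed, {
    stats::kmeans(embedding, centers = k, nstart = n_init, iter.max = 100)
  })
  if (any(km$size == 0)) warning("k-means produced an empty cluster")
  ids <- as.integer(km$cluster) - 1L
  names(ids) <- rownames(embedding)
  ids
}

#' Per-cluster feature profiles
#'
#' Averages each of the four unstandardized tracklet features over all
#' tracklets belonging to each cluster's member tracks, with member counts.
#'
#' @param assignments Integer vector of 0-based cluster ids, one per track,
#'   in the order of `fs$series`.
#' @param fs The `"feature_series_set"` the clustering was built from.
#' @return Data frame with columns `cluster_id`, the four feature means,
#'   `n_tracklets`, `n_tracks`; one row per cluster id present (empty
#'   clusters get count 0 and NA means).
#' @export
profile_clusters <- function(assignments, fs) {
  stopifnot(inherits(fs, "feature_series_set"))
  if (length(assignments) != length(fs$raw_series)) {
    stop("one assignment per track required", call. = FALSE)
  }
  ids <- sort(unique(assignments))
  rows <- lapply(ids, function(cl) {
    member <- which(assignments == cl)
    feats <- do.call(rbind, fs$raw_series[member])
    data.frame(
      cluster_id = cl,
      mean_speed = mean(feats[, "mean_speed"]),
      displacement = mean(feats[, "displacement"]),
      directionality = mean(feats[, "directionality"]),
      arrest_coefficient = mean(feats[, "arrest_coefficient"]),
      n_tracklets = nrow(feats),
      n_tracks = length(member)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ACTION_LABELS <- c(
  "flowing", "directed", "patrolling", "focused_patrolling", "arrested"
)

#' Assign behavioral action labels to cluster profiles
#'
#' Deterministic rule on min-max-normalized cluster profile means, defined
#' for exactly five clusters:
#' the cluster with the highest arrest coefficient is `arrested`; among the
#' rest, the one with the lowest arrest coefficient (ties broken by highest
#' mean speed) is `flowing`; the remaining three are ranked by a composite
#' motility score (mean of normalized speed, directionality and
#' displacement minus normalized arrest) into `directed` (highest),
#' `patrolling` (middle) and `focused_patrolling` (lowest). Residual ties
#' are broken by ascending cluster id.
#'
#' @param profiles Data frame from [profile_clusters()] with exactly 5 rows.
#' @return Named character vector mapping cluster id (as name) to label.
#' @export
annotate_actions <- function(profiles) {
  if (nrow(profiles) != 5) {
    stop("action labeling is defined for exactly 5 cluster profiles", call. = FALSE)
  }
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] == r[1]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  sp <- norm01(profiles$mean_speed)
  di <- norm01(profiles$directionality)
  dp <- norm01(profiles$displacement)
  ar <- norm01(profiles$arrest_coefficient)
  cid <- profiles$cluster_id

  labels <- rep(NA_character_, 5)
  # highest arrest -> arrested; ties by ascending cluster id
  arrested_i <- order(-ar, cid)[1]
  labels[arrested_i] <- "arrested"
  rest <- setdiff(seq_len(5), arrested_i)
  # lowest arrest among the rest -> flowing; ties by highest speed, then id
  flowing_i <- rest[order(ar[rest], -sp[rest], cid[rest])[1]]
  labels[flowing_i] <- "flowing"
  rem <- setdiff(rest, flowing_i)
  score <- (sp + di + dp) / 3 - ar
  ord <- rem[order(-score[rem], cid[rem])]
  labels[ord] <- c("directed", "patrolling", "focused_patrolling")

  stats::setNames(labels, as.character(cid))
}

#' Cluster composition per condition
#'
#' Percentage of each condition's tracks assigned to each cluster; within a
#' condition the percentages sum to 100.
#'
#' @param assignments Integer cluster ids, one per track.
#' @param conditions Character condition labels, one per track.
#' @param labels Optional named map cluster id -> action label (from
#'   [annotate_actions()]), added as a column.
#' @return Data frame with columns `cluster_id`, (`label`,) one column per
#'   condition holding percentages.
#' @export
condition_percentages <- function(assignments, conditions, labels = NULL) {
  if (length(assignments) != length(conditions)) {
    stop("one condition per track required", call. = FALSE)
  }
  if (anyNA(conditions)) stop("every track needs a condition label", call. = FALSE)
  tab <- table(
    cluster_id = factor(assignments, levels = sort(unique(assignments))),
    condition = conditions
  )
  if (any(colSums(tab) == 0)) stop("a condition has zero tracks", call. = FALSE)
  pct <- sweep(tab, 2, colSums(tab), "/") * 100
  out <- data.frame(cluster_id = as.integer(rownames(pct)))
  if (!is.null(labels)) out$label <- unname(labels[as.character(out$cluster_id)])
  for (cn in colnames(pct)) out[[cn]] <- as.numeric(pct[, cn])
  out
}
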