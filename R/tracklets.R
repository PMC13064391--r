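#' Sliding-window tracklets of a track
#'
#' Cuts a track into contiguous fixed-length windows ("tracklets", default
#' 8 points) advanced by `stride`, the unit of behavioral featurization.
#'
#' @param track A [track()] object.
#' @param window Points per tracklet (default 8); at least 2.
#' @param stride Window advance in frames (default 1); at least 1.
#' @return List of `"tracklet"` objects (`parent_id`, `start_index`
#'   (0-based frame offset), `positions`, `dt`). A track shorter than
#'   `window` yields an empty list carrying attribute `too_short = TRUE`.
#' @export
make_tracklets <- function(track, window = 8L, stride = 1L) {
  validate_track(track)
  if (window < 2) stop("`window` must be >= 2", call. = FALSE)
  if (stride < 1) stop("`stride` must be >= 1", call. = FALSE)
  n <- n_points(track)
  if (n < window) {
    out <- list()
    attr(out, "too_short") <- TRUE
    return(out)
  }
  starts <- seq(1L, n - window + 1L, by = stride)
  dt <- track_dt(track)
  lapply(starts, function(s) {
    structure(
      list(
        parent_id = track$track_id,
        start_index = s - 1L,
        positions = track$positions[s:(s + window - 1L), , drop = FALSE],
        dt = dt
      ),
      class = "tracklet"
    )
  })
}

#' Four-parameter tracklet features
#'
#' The multiparametric featurization of one tracklet: mean instantaneous
#' speed (um/min), net displacement from first to last window point (um),
#' directionality (net displacement over within-window path length, 0 when
#' both are 0), and arrest coefficient (fraction of within-window steps
#' slower than `arrest_threshold`).
#'
#' @param tracklet A `"tracklet"` from [make_tracklets()].
#' @param arrest_threshold Arrest speed cutoff, um/min.
#' @return Named numeric vector `mean_speed`, `displacement`,
#'   `directionality`, `arrest_coefficient`.
#' @export
tracklet_features <- function(tracklet, arrest_threshold = 2.0) {
  stopifnot(inherits(tracklet, "tracklet"))
  pos <- tracklet$positions
  steps <- sqrt(rowSums(diff(pos)^2))
  speeds <- steps / tracklet$dt * 60
  path <- sum(steps)
  disp <- sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2))
  c(
    mean_speed = mean(speeds),
    displacement = disp,
    directionality = if (path == 0) 0 else disp / path,
    arrest_coefficient = mean(speeds < arrest_threshold)
  )
}

FEATURE_NAMES <- c("mean_speed", "displacement", "directionality", "arrest_coefficient")

#' Per-track multivariate feature series
#'
#' Builds one ordered sequence of 4-feature vectors per track (one vector
#' per sliding-window position) and standardizes each feature to z-scores
#' across all tracklets of the cohort. The cohort-wide mean and SD are
#' stored so that the same standardization can be re-applied to other data
#' (e.g. when a condition is analyzed in isolation).
#'
#' @param tracks List of [track()] objects (already duration-filtered).
#' @param window,stride Tracklet window and stride, see [make_tracklets()].
#' @param arrest_threshold Arrest cutoff, um/min.
#' @param standardization Optional list with `mean` and `sd` (named numeric
#'   vectors over the four features) to reuse frozen constants instead of
#'   recomputing them from `tracks`.
#' @return Object of class `"feature_series_set"`: list with
#'   `series` (per-track matrices, n_windows x 4, standardized),
#'   `raw_series` (same, unstandardized), `track_ids`, `conditions`,
#'   `standardization` (mean/sd used), `skipped` (ids of tracks shorter
#'   than the window).
#' @export
build_feature_series <- function(tracks, window = 8L, stride = 1L,
                                 arrest_threshold = 2.0,
                                 standardization = NULL) {
  stopifnot(length(tracks) > 0)
  raw <- list()
  ids <- character(0)
  conds <- character(0)
  skipped <- character(0)
  for (tr in tracks) {
    tls <- make_tracklets(tr, window = window, stride = stride)
    if (length(tls) == 0) {
      skipped <- c(skipped, tr$track_id)
      next
    }
    feats <- t(vapply(tls, tracklet_features,
      numeric(4),
      arrest_threshold = arrest_threshold
    ))
    colnames(feats) <- FEATURE_NAMES
    raw[[length(raw) + 1L]] <- feats
    ids <- c(ids, tr$track_id)
    conds <- c(conds, tr$condition)
  }
  if (length(raw) == 0) {
    stop("no track is long enough to form a tracklet window", call. = FALSE)
  }
  all_feats <- do.call(rbind, raw)
  if (is.null(standardization)) {
    mu <- colMeans(all_feats)
    sdv <- apply(all_feats, 2, stats::sd)
    sdv[sdv == 0] <- 1 # constant feature: leave centred values at 0
    standardization <- list(mean = mu, sd = sdv)
  }
  series <- lapply(raw, function(m) {
    sweep(sweep(m, 2, standardization$mean), 2, standardization$sd, "/")
  })
  structure(
    list(
      series = series, raw_series = raw, track_ids = ids,
      conditions = conds, standardization = standardization,
      skipped = skipped, window = as.integer(window),
      stride = as.integer(stride), arrest_threshold = arrest_threshold
    ),
    class = "feature_series_set"
  )
}

#' @export
print.feature_series_set <- function(x, ...) {
  cat(sprintf(
    "<feature_series_set> %d tracks, window %d, stride %d (%d too short)\n",
    length(x$series), x$window, x$stride, length(x$skipped)
  ))
  invisible(x)
}
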