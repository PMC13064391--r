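#' Exclude short tracks
#'
#' Removes tracks observed for fewer than `min_frames` time points. The
#' default of 5 frames reproduces the standard intravital-imaging exclusion
#' of tracks shorter than five timeframes; a track with exactly `min_frames`
#' points is retained (strict "<" rule).
#'
#' @param tracks List of `"track"` objects.
#' @param min_frames Minimum number of time points to retain a track
#'   (default 5). Must be at least 2.
#' @param quiet Suppress the log line stating how many tracks were removed.
#' @return The retained tracks, original order preserved.
#' @export
filter_tracks <- function(tracks, min_frames = 5L, quiet = FALSE) {
  if (!is.numeric(min_frames) || min_frames < 2) {
    stop("`min_frames` must be >= 2", call. = FALSE)
  }
  keep <- vapply(tracks, function(tr) n_points(tr) >= min_frames, logical(1))
  removed <- sum(!keep)
  if (!quiet) {
    message(sprintf(
      "filter_tracks: removed %d of %d tracks (< %d frames)",
      removed, length(tracks), as.integer(min_frames)
    ))
  }
  tracks[keep]
}

#' Instantaneous step speeds of a track
#'
#' Euclidean frame-to-frame displacement divided by the frame interval,
#' converted to micrometers per minute. A track with n points yields n - 1
#' speeds.
#'
#' @param track A `"track"` object.
#' @return Numeric vector of step speeds (um/min).
#' @export
step_speeds <- function(track) {
  validate_track(track)
  d <- sqrt(rowSums(diff(track$positions)^2))
  d / track_dt(track) * 60
}

#' Per-track motility statistics
#'
#' Computes the standard per-track motility measures: duration (time between
#' first and last point, s), length (total path length, um), displacement
#' (straight-line distance between first and last position, um), mean speed
#' (length/duration, um/min), maximum instantaneous speed (um/min),
#' straightness (displacement/length, with 0/0 defined as 0), speed
#' variation (population standard deviation of the instantaneous step
#' speeds, um/min), and arrest coefficient (fraction of steps slower than
#' `arrest_threshold`).
#'
#' @param track A `"track"` object with at least 2 points.
#' @param arrest_threshold Speed cutoff below which a step counts as
#'   arrested, in um/min (default 2).
#' @return A one-row data frame with columns `track_id`, `condition`,
#'   `n_points`, `duration_s`, `length_um`, `displacement_um`,
#'   `mean_speed_um_min`, `max_speed_um_min`, `straightness`,
#'   `speed_variation_um_min`, `arrest_coefficient`.
#' @export
#' @examples
#' tr <- track(1, cbind(c(0, 3, 6), c(0, 4, 8), 0), times = c(0, 60, 120))
#' compute_metrics(tr)
compute_metrics <- function(track, arrest_threshold = 2.0) {
  validate_track(track)
  sp <- step_speeds(track)
  pos <- track$positions
  len <- sum(sqrt(rowSums(diff(pos)^2)))
  disp <- sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2))
  duration <- track$times[length(track$times)] - track$times[1]
  straight <- if (len == 0) 0 else disp / len
  data.frame(
    track_id = track$track_id,
    condition = track$condition,
    n_points = n_points(track),
    duration_s = duration,
    length_um = len,
    displacement_um = disp,
    mean_speed_um_min = len / duration * 60,
    max_speed_um_min = max(sp),
    straightness = straight,
    speed_variation_um_min = sqrt(mean((sp - mean(sp))^2)),
    arrest_coefficient = mean(sp < arrest_threshold),
    stringsAsFactors = FALSE
  )
}

#' Motility statistics for a list of tracks
#'
#' @param tracks List of `"track"` objects.
#' @param arrest_threshold Arrest speed cutoff, um/min.
#' @param planar If `TRUE`, drop the z coordinate before computing metrics.
#' @return Data frame with one row per track (see [compute_metrics()]).
#' @export
compute_metrics_table <- function(tracks, arrest_threshold = 2.0, planar = FALSE) {
  stopifnot(length(tracks) > 0)
  if (planar) tracks <- lapply(tracks, flatten_track)
  out <- do.call(rbind, lapply(tracks, compute_metrics, arrest_threshold = arrest_threshold))
  rownames(out) <- NULL
  out
}

#' Two-group comparison of a motility metric
#'
#' Compares two sets of per-track values with either the Mann-Whitney U test
#' (normal approximation with midranks for ties, no continuity correction,
#' two-sided) or Welch's two-sample t-test.
#'
#' @param values_a,values_b Numeric vectors, each non-empty.
#' @param test `"mann_whitney"` (default) or `"t_test"`.
#' @return List with `statistic` (U for Mann-Whitney, t otherwise),
#'   `p_value`, and `test`.
#' @export
compare_groups <- function(values_a, values_b, test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  if (length(values_a) < 1 || length(values_b) < 1) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (test == "mann_whitney") {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = FALSE)
    )
    list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
  } else {
    ht <- stats::t.test(values_a, values_b)
    list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
  }
}
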