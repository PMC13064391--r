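#' Construct a cell track
#'
#' A track is the time-ordered sequence of centroid positions of one cell,
#' as produced by upstream detection and linking (e.g. an Imaris export).
#' Positions are in micrometers; times in seconds with a uniform frame
#' interval.
#'
#' @param track_id Track identifier (coerced to character).
#' @param positions Numeric matrix with one row per time point and columns
#'   x, y, z (micrometers). A two-column matrix is accepted and padded with
#'   z = 0.
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing with constant spacing.
#' @param condition Optional free-text condition label (e.g. "untreated").
#'
#' @return An object of class `"track"`: a list with elements `track_id`,
#'   `positions`, `times`, `condition`.
#' @export
#' @examples
#' tr <- track(1, cbind(x = c(0, 3, 6), y = c(0, 4, 8), z = 0), times = c(0, 60, 120))
#' n_points(tr)
track <- function(track_id, positions, times, condition = NA_character_) {
  positions <- as.matrix(positions)
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  if (ncol(positions) != 3L) {
    stop("`positions` must have 2 (x, y) or 3 (x, y, z) columns", call. = FALSE)
  }
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  times <- as.numeric(times)
  obj <- structure(
    list(
      track_id = as.character(track_id)[1],
      positions = positions,
      times = times,
      condition = as.character(condition)[1]
    ),
    class = "track"
  )
  validate_track(obj)
}

#' @rdname track
#' @param x Object to test or validate.
#' @export
is_track <- function(x) inherits(x, "track")

#' Validate a track object
#'
#' Checks the track invariants: at least two time points, finite positions,
#' and strictly increasing times with constant spacing (relative tolerance
#' 1e-6 of the frame interval).
#'
#' @param x A `"track"` object.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_track <- function(x) {
  if (!is_track(x)) stop("not a track object", call. = FALSE)
  n <- nrow(x$positions)
  if (n < 2L) stop("track must have at least 2 time points", call. = FALSE)
  if (length(x$times) != n) {
    stop("`times` length must match the number of positions", call. = FALSE)
  }
  if (!all(is.finite(x$positions))) {
    stop(sprintf("track %s has non-finite positions", x$track_id), call. = FALSE)
  }
  if (!all(is.finite(x$times))) {
    stop(sprintf("track %s has non-finite times", x$track_id), call. = FALSE)
  }
  dts <- diff(x$times)
  if (any(dts <= 0)) {
    stop(sprintf("track %s: times must be strictly increasing", x$track_id),
      call. = FALSE
    )
  }
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    stop(sprintf("track %s: non-uniform time spacing", x$track_id), call. = FALSE)
  }
  x
}

#' @rdname track
#' @export
n_points <- function(x) {
  stopifnot(is_track(x))
  nrow(x$positions)
}

#' Frame interval of a track, in seconds
#' @param x A `"track"` object.
#' @return Scalar frame interval (seconds).
#' @export
track_dt <- function(x) {
  stopifnot(is_track(x))
  x$times[2] - x$times[1]
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf(
    "<track %s> %d points, dt = %gs, condition = %s\n",
    x$track_id, n_points(x), track_dt(x), x$condition
  ))
  invisible(x)
}

#' @export
as.data.frame.track <- function(x, ...) {
  data.frame(
    track_id = x$track_id,
    frame = seq_len(n_points(x)),
    time_s = x$times,
    x_um = x$positions[, "x"],
    y_um = x$positions[, "y"],
    z_um = x$positions[, "z"],
    condition = x$condition,
    stringsAsFactors = FALSE
  )
}

#' Combine tracks into a single long table
#'
#' @param tracks List of `"track"` objects.
#' @return A data frame with columns `track_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`, `z_um`, `condition`; one row per (track, frame).
#' @export
tracks_to_table <- function(tracks) {
  stopifnot(is.list(tracks))
  do.call(rbind, lapply(tracks, as.data.frame))
}

#' Drop the z coordinate of a track
#'
#' Projects a track onto the imaging plane by zeroing z; used when metrics
#' should be computed in 2-D.
#'
#' @param x A `"track"` object.
#' @return The track with z set to 0.
#' @export
flatten_track <- function(x) {
  stopifnot(is_track(x))
  x$positions[, "z"] <- 0
  x
}
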