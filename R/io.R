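TRACK_DIALECTS <- list(
  plain = c(
    track_id = "track_id", frame = "frame", time = "time_s",
    x = "x_um", y = "y_um", z = "z_um", condition = "condition"
  ),
  imaris = c(
    track_id = "TrackID", frame = "Time", time = "",
    x = "Position X", y = "Position Y", z = "Position Z", condition = "condition"
  )
)

#' Read cell tracks from CSV
#'
#' Reads a track table in either the package's `plain` dialect
#' (`track_id, frame, time_s, x_um, y_um, z_um[, condition]`) or the
#' `imaris` export dialect (`TrackID, Time, Position X/Y/Z`), or with an
#' explicit column map. Rows are grouped by track id and sorted by time;
#' duplicated (track, frame) pairs and non-numeric coordinates are
#' reported with their file row numbers.
#'
#' @param path CSV file path.
#' @param dialect `"plain"`, `"imaris"`, or a named character vector with
#'   entries `track_id`, `frame`, `x`, `y`, and optionally `time`, `z`,
#'   `condition` mapping to column names ("" = absent).
#' @param dt Frame interval (s) used when the file has no time column.
#' @return List of [track()] objects.
#' @export
read_tracks <- function(path, dialect = "plain", dt = 60) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.character(dialect) && length(dialect) == 1L) {
    if (!dialect %in% names(TRACK_DIALECTS)) {
      stop(sprintf(
        "unknown dialect '%s'; use 'plain', 'imaris', or a column map", dialect
      ), call. = FALSE)
    }
    dialect <- TRACK_DIALECTS[[dialect]]
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x", "y")
  for (key in need) {
    if (!nzchar(dialect[key]) || !dialect[key] %in% names(df)) {
      stop(sprintf("required column '%s' (%s) missing in %s", dialect[key], key, path),
        call. = FALSE
      )
    }
  }
  getcol <- function(key) {
    cn <- dialect[key]
    if (!is.na(cn) && nzchar(cn) && cn %in% names(df)) df[[cn]] else NULL
  }
  for (key in c("x", "y", "z")) {
    v <- getcol(key)
    if (!is.null(v) && !is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf(
        "non-numeric %s coordinate in %s at data row %d", key, path, bad
      ), call. = FALSE)
    }
  }
  tid <- as.character(getcol("track_id"))
  frame <- as.numeric(getcol("frame"))
  dup <- duplicated(paste(tid, frame))
  if (any(dup)) {
    stop(sprintf(
      "duplicate (track, frame) pair at data row %d (track %s, frame %g) in %s",
      which(dup)[1], tid[which(dup)[1]], frame[which(dup)[1]], path
    ), call. = FALSE)
  }
  timec <- getcol("time")
  z <- getcol("z")
  cond <- getcol("condition")
  lapply(split(seq_along(tid), tid), function(rows) {
    rows <- rows[order(frame[rows])]
    times <- if (!is.null(timec)) {
      as.numeric(timec[rows])
    } else {
      (frame[rows] - frame[rows][1]) * dt
    }
    track(
      track_id = tid[rows[1]],
      positions = cbind(
        as.numeric(df[[dialect["x"]]][rows]),
        as.numeric(df[[dialect["y"]]][rows]),
        if (is.null(z)) 0 else as.numeric(z[rows])
      ),
      times = times,
      condition = if (is.null(cond)) NA_character_ else as.character(cond[rows[1]])
    )
  })
}

#' Write cell tracks to CSV (plain dialect)
#'
#' @param tracks List of [track()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks_to_table(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default: frame interval
#' `dt` (60 s), `pixel_size` (um/px), duration filter `min_frames` (5),
#' tracklet `window` (8) and `stride` (1), `arrest_threshold` (2 um/min),
#' number of clusters `k` (5), erosion `band_spacing` (40 um), the master
#' `seed`, and parameter blocks for UMAP (`n_neighbors`, `min_dist`),
#' k-means (`n_init`) and optical flow ([flow_params()]). Unknown keys are
#' rejected.
#'
#' @param ... Overrides of the defaults.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- list(
    dt = 60, pixel_size = 1, min_frames = 5L, window = 8L, stride = 1L,
    arrest_threshold = 2.0, k = 5L, band_spacing = 40, seed = 1L,
    umap = list(n_neighbors = 15L, min_dist = 0.1),
    kmeans = list(n_init = 10L),
    flow = unclass(flow_params()),
    dialect = "plain"
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
      call. = FALSE
    )
  }
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]])) {
      sub_unknown <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (length(sub_unknown) > 0) {
        stop(sprintf(
          "unknown config keys in '%s': %s", nm, paste(sub_unknown, collapse = ", ")
        ), call. = FALSE)
      }
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path A .yaml/.yml or .json file whose keys match [run_config()].
#' @return A `"run_config"` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
  run_config(vals)
}
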