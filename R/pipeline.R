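#' Behavioral action recognition for a track cohort
#'
#' One-stop composition of the action-recognition stage: sliding-window
#' tracklets, four-feature series with cohort standardization, DTW
#' cross-distance matrix, 2-D UMAP embedding, k-means clustering and (for
#' k = 5) rule-based action labels. Tracks are processed in canonical
#' order (sorted by track id) so the result does not depend on input
#' order.
#'
#' @param tracks List of [track()] objects (already duration-filtered).
#' @param window,stride,arrest_threshold Tracklet settings.
#' @param k Number of clusters (default 5).
#' @param seed Integer seed driving UMAP and k-means.
#' @param n_neighbors,min_dist UMAP settings.
#' @param n_init k-means restarts.
#' @return List of class `"action_result"`: `assignments` (data frame
#'   `track_id`, `condition`, `u1`, `u2`, `cluster_id`, `label`),
#'   `profiles`, `labels` (cluster id to label map, `NULL` unless k = 5),
#'   `percentages` (per-condition, `NULL` without conditions), `features`
#'   (the `"feature_series_set"`), `distance` (DTW matrix), `skipped`.
#' @export
recognize_actions <- function(tracks, window = 8L, stride = 1L,
                              arrest_threshold = 2.0, k = 5L, seed = 1L,
                              n_neighbors = 15L, min_dist = 0.1,
                              n_init = 10L) {
  ids <- vapply(tracks, function(tr) tr$track_id, character(1))
  tracks <- tracks[order(ids)]
  fs <- build_feature_series(tracks,
    window = window, stride = stride,
    arrest_threshold = arrest_threshold
  )
  D <- cross_distance_matrix(fs)
  n_neighbors <- min(n_neighbors, nrow(D) - 1L)
  emb <- embed_2d(D,
    seed = derive_seed(seed, 1L),
    n_neighbors = n_neighbors, min_dist = min_dist
  )
  cl <- cluster_tracks(emb, k = k, seed = derive_seed(seed, 2L), n_init = n_init)
  profiles <- profile_clusters(cl, fs)
  labels <- if (k == 5L) annotate_actions(profiles) else NULL
  assignments <- data.frame(
    track_id = fs$track_ids,
    condition = fs$conditions,
    u1 = emb[, 1], u2 = emb[, 2],
    cluster_id = unname(cl),
    label = if (is.null(labels)) NA_character_ else unname(labels[as.character(cl)]),
    stringsAsFactors = FALSE
  )
  rownames(assignments) <- NULL
  percentages <- if (!anyNA(fs$conditions)) {
    condition_percentages(assignments$cluster_id, assignments$condition, labels)
  } else {
    NULL
  }
  structure(
    list(
      assignments = assignments, profiles = profiles, labels = labels,
      percentages = percentages, features = fs, distance = D,
      skipped = fs$skipped,
      params = list(
        window = window, stride = stride, arrest_threshold = arrest_threshold,
        k = k, seed = seed, n_neighbors = n_neighbors, min_dist = min_dist,
        n_init = n_init
      )
    ),
    class = "action_result"
  )
}

#' @export
print.action_result <- function(x, ...) {
  cat(sprintf(
    "<action_result> %d tracks in %d clusters%s\n",
    nrow(x$assignments), nrow(x$profiles),
    if (!is.null(x$labels)) {
      paste0(" (", paste(x$labels, collapse = ", "), ")")
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Run the full motility pipeline
#'
#' Executes duration filtering, per-track motility metrics (with
#' between-condition tests when two or more conditions are present),
#' behavioral action recognition, and — when a timelapse and tumor mask
#' are supplied — optical-flow motility mapping over concentric erosion
#' bands. All outputs and a JSON run manifest are written to `out_dir`.
#'
#' @param config A [run_config()].
#' @param tracks Either a path to a track CSV (read with
#'   `config$dialect`) or a list of [track()] objects.
#' @param out_dir Output directory (created if needed).
#' @param images_path,mask_path Optional timelapse TIFF and tumor mask
#'   TIFF; the spatial stage is skipped when absent.
#' @param images_post_path Optional second (post-treatment) timelapse; with
#'   it the spatial stage emits a paired before/after band table.
#' @param quiet Suppress per-stage log lines.
#' @return `out_dir`, invisibly. Files written: `metrics.csv`,
#'   `group_tests.json` (if >= 2 conditions), `embedding.csv`,
#'   `cluster_profiles.csv`, `condition_percentages.csv` (if conditions),
#'   `band_motility.csv` + `motility_map.tif` (spatial stage), and
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, tracks, out_dir,
                         images_path = NULL, mask_path = NULL,
                         images_post_path = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list())

  if (is.character(tracks)) {
    tracks <- read_tracks(tracks, dialect = config$dialect, dt = config$dt)
  }
  n_input <- length(tracks)
  log_stage("read", "%d tracks", n_input, quiet = quiet)

  kept <- filter_tracks(tracks, min_frames = config$min_frames, quiet = TRUE)
  n_filtered <- length(kept)
  log_stage(
    "filter", "%d/%d tracks pass the %d-frame duration filter",
    n_filtered, n_input, config$min_frames,
    quiet = quiet
  )
  if (n_filtered == 0) stop("no tracks pass the duration filter", call. = FALSE)

  metrics <- compute_metrics_table(kept, arrest_threshold = config$arrest_threshold)
  metrics <- metrics[order(metrics$track_id), , drop = FALSE]
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  conds <- unique(metrics$condition[!is.na(metrics$condition)])
  if (length(conds) >= 2) {
    metric_cols <- c(
      "mean_speed_um_min", "max_speed_um_min", "length_um", "displacement_um",
      "speed_variation_um_min", "straightness", "arrest_coefficient"
    )
    tests <- lapply(metric_cols, function(mc) {
      a <- metrics[[mc]][metrics$condition == conds[1]]
      b <- metrics[[mc]][metrics$condition == conds[2]]
      ht <- compare_groups(a, b, "mann_whitney")
      list(
        metric = mc, group_a = conds[1], group_b = conds[2],
        mean_a = mean(a), mean_b = mean(b),
        statistic = ht$statistic, p_value = ht$p_value
      )
    })
    jsonlite::write_json(tests, file.path(out_dir, "group_tests.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  act <- recognize_actions(kept,
    window = config$window, stride = config$stride,
    arrest_threshold = config$arrest_threshold, k = config$k,
    seed = config$seed, n_neighbors = config$umap$n_neighbors,
    min_dist = config$umap$min_dist, n_init = config$kmeans$n_init
  )
  n_action <- nrow(act$assignments)
  log_stage(
    "actions", "%d tracks clustered into %d groups (%d too short for window %d)",
    n_action, nrow(act$profiles), length(act$skipped), config$window,
    quiet = quiet
  )
  utils::write.csv(act$assignments, file.path(out_dir, "embedding.csv"),
    row.names = FALSE
  )
  utils::write.csv(act$profiles, file.path(out_dir, "cluster_profiles.csv"),
    row.names = FALSE
  )
  if (!is.null(act$percentages)) {
    utils::write.csv(act$percentages,
      file.path(out_dir, "condition_percentages.csv"),
      row.names = FALSE
    )
  }

  spatial_run <- FALSE
  if (!is.null(images_path) && !is.null(mask_path)) {
    seq_pre <- read_timelapse(images_path,
      pixel_size = config$pixel_size, dt = config$dt
    )
    mask <- read_mask(mask_path)
    fp <- do.call(flow_params, config$flow)
    if (!is.null(images_post_path)) {
      seq_post <- read_timelapse(images_post_path,
        pixel_size = config$pixel_size, dt = config$dt
      )
      bt <- before_after_bands(seq_pre, seq_post, mask,
        spacing_um = config$band_spacing, params = fp
      )
      mm <- motility_map(seq_post, fp)
    } else {
      mm <- motility_map(seq_pre, fp)
      bands <- erode_bands(mask,
        spacing_um = config$band_spacing,
        pixel_size = seq_pre$pixel_size
      )
      bt <- band_motility(mm, bands)
    }
    utils::write.csv(bt, file.path(out_dir, "band_motility.csv"), row.names = FALSE)
    tiff::writeTIFF(mm$values, file.path(out_dir, "motility_map.tif"),
      bits.per.sample = 32L
    )
    spatial_run <- TRUE
    log_stage("spatial", "%d erosion bands quantified", nrow(bt), quiet = quiet)
  } else {
    log_stage("spatial", "skipped (no images/mask supplied)", quiet = quiet)
  }

  manifest$stages <- list(
    n_input = n_input,
    n_after_duration_filter = n_filtered,
    n_after_tracklet_filter = n_action,
    tracklet_skipped_ids = act$skipped,
    spatial = if (spatial_run) "run" else "skipped"
  )
  manifest$cluster_labels <- as.list(act$labels)
  manifest$standardization <- lapply(act$features$standardization, as.list)
  manifest$package_version <- as.character(utils::packageVersion("ivmmotility"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' Collates the CSV outputs of [run_pipeline()] into a plain-text report:
#' per-condition metric summaries (with test p-values when available),
#' cluster profiles with action labels, per-condition cluster percentages,
#' and the band-motility table. Values are re-read from the run outputs,
#' never recomputed.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param path Output file (default `report.md` inside `run_dir`).
#' @return The report path, invisibly.
#' @export
write_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  lines <- c("# Motility pipeline report", "")
  fmt_table <- function(df) {
    txt <- utils::capture.output(print(df, row.names = FALSE))
    c(paste0("    ", txt), "")
  }
  mfile <- file.path(run_dir, "metrics.csv")
  if (file.exists(mfile)) {
    metrics <- utils::read.csv(mfile)
    lines <- c(lines, sprintf("## Track metrics (%d tracks)", nrow(metrics)), "")
    num <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
    num <- setdiff(num, "n_points")
    by_cond <- split(metrics, if (all(is.na(metrics$condition))) {
      rep("all", nrow(metrics))
    } else {
      metrics$condition
    })
    summ <- do.call(rbind, lapply(names(by_cond), function(cn) {
      data.frame(
        condition = cn, n = nrow(by_cond[[cn]]),
        t(round(colMeans(by_cond[[cn]][num]), 3))
      )
    }))
    lines <- c(lines, fmt_table(summ))
  } else {
    lines <- c(lines, "## Track metrics: MISSING", "")
  }
  gfile <- file.path(run_dir, "group_tests.json")
  if (file.exists(gfile)) {
    tests <- jsonlite::read_json(gfile, simplifyVector = TRUE)
    lines <- c(lines, "## Group comparisons (Mann-Whitney)", "")
    lines <- c(lines, fmt_table(tests[c("metric", "mean_a", "mean_b", "p_value")]))
  }
  pfile <- file.path(run_dir, "cluster_profiles.csv")
  efile <- file.path(run_dir, "embedding.csv")
  if (file.exists(pfile) && file.exists(efile)) {
    profiles <- utils::read.csv(pfile)
    emb <- utils::read.csv(efile)
    lab <- unique(emb[c("cluster_id", "label")])
    profiles <- merge(profiles, lab, by = "cluster_id", sort = TRUE)
    lines <- c(lines, "## Behavioral clusters", "", fmt_table(profiles))
  } else {
    lines <- c(lines, "## Behavioral clusters: MISSING", "")
  }
  cfile <- file.path(run_dir, "condition_percentages.csv")
  if (file.exists(cfile)) {
    lines <- c(
      lines, "## Cluster percentages per condition", "",
      fmt_table(utils::read.csv(cfile))
    )
  }
  bfile <- file.path(run_dir, "band_motility.csv")
  if (file.exists(bfile)) {
    lines <- c(
      lines, "## Band motility (peripheral to deep)", "",
      fmt_table(utils::read.csv(bfile))
    )
  } else {
    lines <- c(lines, "## Band motility: not run", "")
  }
  writeLines(lines, path)
  invisible(path)
}
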