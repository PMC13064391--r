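make_block_distance <- function(sizes, within = 1, between = 20, seed = 1) {
  n <- sum(sizes)
  set.seed(seed)
  block <- rep(seq_along(sizes), sizes)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      base <- if (block[i] == block[j]) within else between
      D[i, j] <- D[j, i] <- base * runif(1, 0.5, 1.5)
    }
  }
  list(D = D, block = block)
}

test_that("the embedding is 2-D, seeded, and preserves block structure", {
  bl <- make_block_distance(c(20, 20), seed = 11)
  emb <- embed_2d(bl$D, seed = 5, n_neighbors = 10)
  expect_equal(dim(emb), c(40, 2))
  expect_identical(emb, embed_2d(bl$D, seed = 5, n_neighbors = 10))
  # nearest embedded neighbour stays within the block for >= 90% of points
  ed <- as.matrix(dist(emb))
  diag(ed) <- Inf
  nn <- apply(ed, 1, which.min)
  expect_gte(mean(bl$block[nn] == bl$block), 0.9)
  expect_error(embed_2d(bl$D, n_neighbors = 45), "n_neighbors")
})

test_that("k-means recovers separable blobs and respects k", {
  set.seed(3)
  blob1 <- cbind(rnorm(25), rnorm(25))
  blob2 <- cbind(rnorm(25) + 50, rnorm(25))
  emb <- rbind(blob1, blob2)
  cl <- cluster_tracks(emb, k = 2, seed = 4)
  expect_setequal(unique(cl), c(0L, 1L))
  expect_length(unique(cl[1:25]), 1)
  expect_length(unique(cl[26:50]), 1)
  expect_true(cl[1] != cl[26])
  one <- cluster_tracks(emb, k = 1, seed = 4)
  expect_true(all(one == 0L))
  expect_error(cluster_tracks(emb[1:3, ], k = 5, seed = 1), "< k")
})

test_that("cluster profiles are tracklet-weighted means with conserved counts", {
  tracks <- lapply(1:5, function(i) random_track(9 + i, seed = 60 + i))
  fs <- build_feature_series(tracks)
  # single cluster: profile equals the cohort mean
  prof1 <- profile_clusters(rep(0L, 5), fs)
  all_raw <- do.call(rbind, fs$raw_series)
  expect_equal(prof1$mean_speed, mean(all_raw[, "mean_speed"]))
  expect_equal(prof1$n_tracklets, nrow(all_raw))
  # hand-built two-cluster split
  asg <- c(0L, 0L, 1L, 1L, 1L)
  prof <- profile_clusters(asg, fs)
  manual0 <- do.call(rbind, fs$raw_series[1:2])
  manual1 <- do.call(rbind, fs$raw_series[3:5])
  expect_equal(prof$displacement, c(
    mean(manual0[, "displacement"]),
    mean(manual1[, "displacement"])
  ))
  expect_equal(sum(prof$n_tracklets), nrow(all_raw))
  expect_equal(prof$n_tracks, c(2L, 3L))
})

test_that("action labels follow the profile-ranking rule", {
  # exaggerated profiles mimicking the five canonical behaviors
  profiles <- data.frame(
    cluster_id = 0:4,
    mean_speed = c(16, 1, 5, 0.1, 9),
    displacement = c(100, 5, 20, 0.5, 60),
    directionality = c(0.9, 0.5, 0.55, 0.4, 0.95),
    arrest_coefficient = c(0.01, 0.65, 0.2, 1, 0.05),
    n_tracklets = 10, n_tracks = 2
  )
  labels <- annotate_actions(profiles)
  expect_equal(unname(labels["0"]), "flowing") # lowest arrest, highest speed
  expect_equal(unname(labels["3"]), "arrested") # highest arrest
  expect_equal(unname(labels["4"]), "directed")
  expect_equal(unname(labels["2"]), "patrolling")
  expect_equal(unname(labels["1"]), "focused_patrolling")

  # five identical profiles: deterministic id-ordered tie-break
  flat <- profiles
  flat[, 2:5] <- 1
  tie <- annotate_actions(flat)
  expect_equal(
    unname(tie[as.character(0:4)]),
    c("arrested", "flowing", "directed", "patrolling", "focused_patrolling")
  )
  expect_identical(tie, annotate_actions(flat))
  expect_error(annotate_actions(profiles[1:4, ]), "exactly 5")
})

test_that("condition percentages count tracks and sum to 100", {
  asg <- c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L)
  cond <- rep(c("untreated", "treated"), each = 4)
  pct <- condition_percentages(asg, cond)
  expect_equal(pct$untreated, c(75, 25))
  expect_equal(pct$treated, c(25, 75))
  expect_equal(sum(pct$untreated), 100, tolerance = 1e-9)
  expect_equal(sum(pct$treated), 100, tolerance = 1e-9)
  one <- condition_percentages(c(2L, 2L), c("a", "a"))
  expect_equal(one[[2]], 100)
  expect_error(condition_percentages(asg, cond[1:3]), "one condition per track")
  expect_error(condition_percentages(asg, rep(NA_character_, 8)), "condition")
})
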