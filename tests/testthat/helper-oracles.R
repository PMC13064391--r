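# Independent oracles and fixture builders. Everything here recomputes
# quantities from first principles with plain loops, deliberately avoiding
# the package's vectorized code paths.

# random track with positions drawn independently per axis
random_track <- function(n, seed, dt = 60, scale = 10, id = paste0("rnd", seed),
                         condition = NA_character_) {
  set.seed(seed)
  track(
    track_id = id,
    positions = matrix(stats::runif(3 * n, -scale, scale), ncol = 3),
    times = (seq_len(n) - 1) * dt,
    condition = condition
  )
}

# brute-force recomputation of all per-track statistics
oracle_metrics <- function(pos, times, arrest_threshold = 2.0) {
  n <- nrow(pos)
  dt <- times[2] - times[1]
  steps <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    s <- 0
    for (k in 1:3) s <- s + (pos[i + 1, k] - pos[i, k])^2
    steps[i] <- sqrt(s)
  }
  speeds <- steps / dt * 60
  len <- sum(steps)
  disp <- sqrt(sum((pos[n, ] - pos[1, ])^2))
  dur <- times[n] - times[1]
  list(
    duration_s = dur,
    length_um = len,
    displacement_um = disp,
    mean_speed_um_min = len / dur * 60,
    max_speed_um_min = max(speeds),
    straightness = if (len == 0) 0 else disp / len,
    speed_variation_um_min = sqrt(sum((speeds - mean(speeds))^2) / length(speeds)),
    arrest_coefficient = sum(speeds < arrest_threshold) / length(speeds)
  )
}

# exhaustive DTW: minimum cumulative cost over every monotone warping path
# (feasible for series up to length ~6)
oracle_dtw <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1)
  n <- nrow(a)
  m <- nrow(b)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + sqrt(sum((a[i, ] - b[j, ])^2))
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) rec(i + 1L, j, acc)
    if (j < m) rec(i, j + 1L, acc)
    if (i < n && j < m) rec(i + 1L, j + 1L, acc)
  }
  rec(1L, 1L, 0)
  best
}

# two-sided permutation p-value for the Mann-Whitney U statistic
oracle_permutation_p <- function(a, b, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  mu <- na * length(b) / 2
  obs <- abs(u_stat(a, b) - mu)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    idx <- sample(length(pooled), na)
    if (abs(u_stat(pooled[idx], pooled[-idx]) - mu) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# small rendered scene: one blob translating at `vx` px/frame along x
translating_blob_seq <- function(vx, n_frames = 8, h = 64, w = 64, psf = 3,
                                 noise_sd = 0.2, seed = 5, pixel_size = 1) {
  x0 <- w / 2 - vx * (n_frames - 1) / 2
  sp <- render_spec(
    image_shape = c(h, w), pixel_size = pixel_size, psf_sigma = psf,
    amplitude = 100, background = 10, noise_sd = noise_sd,
    tumor_center = c(w / 2, h / 2), tumor_radius = min(h, w) / 4
  )
  tr <- track(
    "blob",
    cbind((x0 + vx * (0:(n_frames - 1)) - 1) * pixel_size, (h / 2 - 1) * pixel_size, 0),
    times = (0:(n_frames - 1)) * 60
  )
  list(seq = render_timelapse(list(tr), sp, seed = seed), spec = sp, track = tr)
}

rot90cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

expect_file_identical <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
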