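test_that("the duration filter applies the strict five-frame rule", {
  t4 <- random_track(4, seed = 1)
  t5 <- random_track(5, seed = 2)
  t9 <- random_track(9, seed = 3)
  kept <- filter_tracks(list(t4, t5, t9), quiet = TRUE)
  expect_equal(
    vapply(kept, function(tr) tr$track_id, character(1)),
    c(t5$track_id, t9$track_id)
  )
  expect_equal(filter_tracks(list(), quiet = TRUE), list())
  expect_error(filter_tracks(list(t5), min_frames = 1), ">= 2")
  expect_message(filter_tracks(list(t4, t5)), "removed 1 of 2")
})

test_that("step speeds match hand geometry and a brute-force oracle", {
  still <- track("s", matrix(2, 3, 3), times = c(0, 60, 120))
  expect_equal(step_speeds(still), c(0, 0))
  tri <- track("t", rbind(c(0, 0, 0), c(3, 4, 0)), times = c(0, 60))
  expect_equal(step_speeds(tri), 5) # 3-4-5 triangle at dt = 60 s
  rnd <- random_track(10, seed = 31)
  manual <- vapply(1:9, function(i) {
    sqrt(sum((rnd$positions[i + 1, ] - rnd$positions[i, ])^2)) / 60 * 60
  }, numeric(1))
  expect_equal(step_speeds(rnd), manual, tolerance = 1e-12)
})

test_that("compute_metrics reproduces closed-form toy trajectories", {
  lin <- track("lin", rbind(c(0, 0, 0), c(3, 4, 0), c(6, 8, 0)),
    times = c(0, 60, 120)
  )
  m <- compute_metrics(lin)
  expect_equal(m$length_um, 10)
  expect_equal(m$displacement_um, 10)
  expect_equal(m$straightness, 1)
  expect_equal(m$duration_s, 120)
  expect_equal(m$mean_speed_um_min, 5)
  expect_equal(m$speed_variation_um_min, 0)

  back <- track("back", rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0)),
    times = c(0, 60, 120)
  )
  mb <- compute_metrics(back, arrest_threshold = 2)
  expect_equal(mb$length_um, 10)
  expect_equal(mb$displacement_um, 0)
  expect_equal(mb$straightness, 0)
  expect_equal(mb$arrest_coefficient, 0)
})

test_that("compute_metrics agrees with the brute-force oracle on random tracks", {
  for (seed in 1:20) {
    tr <- random_track(20, seed = seed)
    m <- compute_metrics(tr, arrest_threshold = 30)
    o <- oracle_metrics(tr$positions, tr$times, arrest_threshold = 30)
    for (f in names(o)) {
      expect_equal(m[[f]], o[[f]], tolerance = 1e-9, label = f)
    }
  }
})

test_that("metrics respect geometric and temporal invariances", {
  base <- random_track(15, seed = 77)
  m0 <- compute_metrics(base)
  # global translation
  shifted <- base
  shifted$positions <- sweep(base$positions, 2, c(100, -50, 3), `+`)
  m1 <- compute_metrics(shifted)
  # rotation about z
  th <- 0.7
  rot <- diag(3)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rotated <- base
  rotated$positions <- base$positions %*% rot
  m2 <- compute_metrics(rotated)
  # time-origin shift
  tshift <- base
  tshift$times <- base$times + 900
  m3 <- compute_metrics(tshift)
  num <- vapply(m0, is.numeric, logical(1))
  for (m in list(m1, m2, m3)) {
    expect_equal(m[num], m0[num], tolerance = 1e-9)
  }
  # doubling dt halves speeds, doubles duration, keeps geometry
  slower <- base
  slower$times <- base$times * 2
  ms <- compute_metrics(slower)
  expect_equal(ms$duration_s, 2 * m0$duration_s)
  expect_equal(ms$length_um, m0$length_um)
  expect_equal(ms$displacement_um, m0$displacement_um)
  expect_equal(ms$mean_speed_um_min, m0$mean_speed_um_min / 2)
  expect_equal(ms$max_speed_um_min, m0$max_speed_um_min / 2)
  expect_equal(ms$speed_variation_um_min, m0$speed_variation_um_min / 2)
})

test_that("per-track bounds hold on simulated cohorts", {
  co <- simulate_cohort(n_per_archetype = 8, seed = 5)
  m <- compute_metrics_table(co$tracks)
  expect_true(all(m$displacement_um <= m$length_um + 1e-9))
  expect_true(all(m$straightness >= 0 & m$straightness <= 1))
  expect_true(all(m$mean_speed_um_min <= m$max_speed_um_min + 1e-9))
  expect_true(all(m$arrest_coefficient >= 0 & m$arrest_coefficient <= 1))
})

test_that("group comparison follows the documented test dialect", {
  same <- c(1, 2, 3)
  res <- compare_groups(same, same)
  expect_equal(res$p_value, 1)
  sep <- compare_groups(c(1, 2, 3), c(101, 102, 103))
  expect_equal(unname(sep$statistic), 0) # U = 0 for the lower group
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
  tt <- compare_groups(c(1, 2, 3, 4), c(2, 3, 4, 5), test = "t_test")
  expect_true(tt$p_value > 0 && tt$p_value < 1)
})

test_that("the Mann-Whitney p approximates a permutation null", {
  set.seed(19)
  a <- rnorm(15, 0)
  b <- rnorm(15, 0.8)
  p_pkg <- compare_groups(a, b)$p_value
  p_perm <- oracle_permutation_p(a, b, n_perm = 1e4, seed = 3)
  expect_lt(abs(p_pkg - p_perm), 0.02)
})
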