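disk_mask <- function(size, radius, centre = (size + 1) / 2) {
  d2 <- outer((seq_len(size) - centre)^2, (seq_len(size) - centre)^2, `+`)
  d2 <= radius^2
}

test_that("erosion bands of a disk match the analytic annulus oracle", {
  mask <- disk_mask(71, 25)
  bands <- erode_bands(mask, spacing_um = 10, pixel_size = 1)
  expect_length(bands$bands, 3)
  expect_equal(bands$labels, c("I", "II", "III"))
  # analytic oracle: band i collects radii in (R - (i+1)s, R - i*s],
  # up to +-2 px of raster discretization at each boundary
  centre <- 36
  r <- sqrt(outer((seq_len(71) - centre)^2, (seq_len(71) - centre)^2, `+`))
  edges <- c(25, 15, 5, -Inf)
  for (i in 1:3) {
    annulus_inner <- r <= edges[i] - 2 & r > max(edges[i + 1] + 2, 0)
    expect_true(all(bands$bands[[i]][annulus_inner]),
      label = sprintf("band %d contains its safe annulus", i)
    )
    outside <- r > edges[i] + 2 | r <= if (is.finite(edges[i + 1])) edges[i + 1] - 2 else -1
    expect_true(!any(bands$bands[[i]][outside & mask]),
      label = sprintf("band %d excludes pixels away from its annulus", i)
    )
  }
})

test_that("band decomposition partitions the mask exactly", {
  for (radius in c(15, 30, 47, 60)) {
    mask <- disk_mask(2 * 60 + 11, radius)
    bands <- erode_bands(mask, spacing_um = 10, pixel_size = 1)
    stacked <- Reduce(`+`, lapply(bands$bands, function(b) b * 1L))
    expect_true(all(stacked[mask] == 1L)) # disjoint cover of the mask
    expect_true(all(stacked[!mask] == 0L))
    # band count agrees with the analytic erosion count for a disk:
    # erosions survive while i * spacing < max inscribed radius
    dm <- as.matrix(EBImage::imageData(
      EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
    ))
    expect_equal(length(bands$bands), floor((max(dm) - 1e-9) / 10) + 1)
  }
})

test_that("spacing at least the disk radius yields the mask itself", {
  mask <- disk_mask(41, 12)
  bands <- erode_bands(mask, spacing_um = 15, pixel_size = 1)
  expect_length(bands$bands, 1)
  expect_identical(bands$bands[[1]], mask)
  expect_error(erode_bands(mask & FALSE, 10, 1), "empty")
  expect_error(erode_bands(mask, 0.4, 1), "below one pixel")
})

test_that("micrometer spacing is converted through the pixel size", {
  mask <- disk_mask(81, 30)
  b2 <- erode_bands(mask, spacing_um = 40, pixel_size = 2) # 20 px spacing
  expect_equal(b2$spacing_px, 20)
  expect_length(b2$bands, 2)
})

test_that("band means average the map over each region", {
  mask <- disk_mask(61, 22)
  bands <- erode_bands(mask, spacing_um = 8, pixel_size = 1)
  # uniform map: every band mean equals the constant
  uni <- matrix(0.37, 61, 61)
  bm <- band_motility(uni, bands)
  expect_true(all(bm$mean == 0.37))
  expect_equal(sum(bm$pixel_count), sum(mask))
  # indicator of the core: core mean 1, others 0
  core <- bands$bands[[length(bands$bands)]]
  ind <- matrix(0, 61, 61)
  ind[core] <- 1
  bmi <- band_motility(ind, bands)
  expect_equal(bmi$mean, c(rep(0, length(bands$bands) - 1), 1))
  # radial gradient: means match direct per-pixel averaging
  r <- sqrt(outer((seq_len(61) - 31)^2, (seq_len(61) - 31)^2, `+`))
  grad <- r / max(r)
  bg <- band_motility(grad, bands)
  manual <- vapply(bands$bands, function(b) mean(grad[b]), numeric(1))
  expect_equal(bg$mean, manual, tolerance = 1e-12)
  expect_error(band_motility(matrix(0, 10, 10), bands), "shapes")
})

test_that("before/after tables pair identical decompositions", {
  sc <- translating_blob_seq(vx = 2, n_frames = 5, noise_sd = 0.1)
  mask <- disk_mask(64, 14, centre = 32.5)
  tab <- before_after_bands(sc$seq, sc$seq, mask, spacing_um = 7)
  expect_equal(tab$mean_pre, tab$mean_post)
  expect_equal(nrow(tab), length(erode_bands(mask, 7, 1)$bands))
  expect_error(
    before_after_bands(sc$seq, sc$seq, matrix(TRUE, 10, 10), 7),
    "geometry"
  )
})
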