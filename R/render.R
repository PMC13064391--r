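#' Rendering specification for synthetic timelapses
#'
#' @param image_shape Integer (height, width) in pixels.
#' @param pixel_size Pixel size, um/px.
#' @param psf_sigma Gaussian blob sigma, px (an effective point-spread
#'   width, not a physical PSF model).
#' @param amplitude Peak blob intensity above background.
#' @param background Constant background intensity.
#' @param noise_sd SD of additive Gaussian noise (0 disables noise).
#' @param tumor_center Tumor disk center, (x px, y px).
#' @param tumor_radius Tumor disk radius, px; the disk must fit in the frame.
#' @return Object of class `"render_spec"`.
#' @export
render_spec <- function(image_shape = c(128L, 128L), pixel_size = 2,
                        psf_sigma = 2, amplitude = 100, background = 10,
                        noise_sd = 2, tumor_center = NULL, tumor_radius = 40) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1)) {
    stop("`image_shape` must be two positive integers (height, width)", call. = FALSE)
  }
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (psf_sigma <= 0) stop("`psf_sigma` must be > 0", call. = FALSE)
  if (is.null(tumor_center)) tumor_center <- rev(image_shape) / 2
  if (tumor_radius < 0) stop("`tumor_radius` must be >= 0", call. = FALSE)
  if (tumor_center[1] - tumor_radius < 1 - 0.5 ||
    tumor_center[1] + tumor_radius > image_shape[2] + 0.5 ||
    tumor_center[2] - tumor_radius < 1 - 0.5 ||
    tumor_center[2] + tumor_radius > image_shape[1] + 0.5) {
    stop("tumor disk must fit within the frame", call. = FALSE)
  }
  structure(
    list(
      image_shape = image_shape, pixel_size = pixel_size,
      psf_sigma = psf_sigma, amplitude = amplitude, background = background,
      noise_sd = noise_sd, tumor_center = as.numeric(tumor_center),
      tumor_radius = tumor_radius
    ),
    class = "render_spec"
  )
}

#' Timelapse image sequence container
#'
#' @param frames Numeric array of dimension (height, width, n_frames).
#' @param pixel_size um/px.
#' @param dt Seconds per frame.
#' @return Object of class `"image_sequence"`.
#' @export
image_sequence <- function(frames, pixel_size, dt) {
  frames <- as.array(frames)
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L) {
    stop("`frames` must be a (height, width, time) array", call. = FALSE)
  }
  if (any(!is.finite(frames)) || any(frames < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(frames = frames, pixel_size = pixel_size, dt = dt),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_sequence> %d frames of %dx%d px, %g um/px, dt = %gs\n",
    d[3], d[1], d[2], x$pixel_size, x$dt
  ))
  invisible(x)
}

# micrometer (x, y) -> fractional pixel (col, row), origin at the centre of
# the top-left pixel (pixel centres at integer coordinates starting at 1)
um_to_px <- function(xy_um, pixel_size) xy_um / pixel_size + 1

#' Render tracks into a noisy timelapse
#'
#' Each frame is the sum of isotropic Gaussian blobs (sigma `psf_sigma`,
#' peak `amplitude`) centred at each cell's position for that frame, plus
#' the constant `background`, plus seeded Gaussian noise of SD `noise_sd`,
#' clipped at 0. Cells are drawn only on frames where their track has a
#' position.
#'
#' @param tracks List of [track()] objects; all coordinates, divided by
#'   `pixel_size`, must fall inside the image bounds.
#' @param spec A [render_spec()].
#' @param seed Integer seed for the noise.
#' @return An [image_sequence()] with as many frames as the longest track.
#' @export
render_timelapse <- function(tracks, spec, seed = 1L) {
  stopifnot(inherits(spec, "render_spec"))
  h <- spec$image_shape[1]
  w <- spec$image_shape[2]
  n_frames <- if (length(tracks) == 0) 1L else max(vapply(tracks, n_points, integer(1)))
  for (tr in tracks) {
    pc <- um_to_px(tr$positions[, c("x", "y"), drop = FALSE], spec$pixel_size)
    if (any(pc[, 1] < 0.5 | pc[, 1] > w + 0.5 | pc[, 2] < 0.5 | pc[, 2] > h + 0.5)) {
      stop(sprintf("track %s extends outside the %dx%d frame", tr$track_id, h, w),
        call. = FALSE
      )
    }
  }
  rows <- seq_len(h)
  cols <- seq_len(w)
  s2 <- 2 * spec$psf_sigma^2
  dt <- if (length(tracks) > 0) track_dt(tracks[[1]]) else 60
  frames <- with_seed(seed, {
    arr <- array(spec$background, dim = c(h, w, n_frames))
    for (t in seq_len(n_frames)) {
      for (tr in tracks) {
        if (n_points(tr) < t) next
        pc <- um_to_px(tr$positions[t, c("x", "y")], spec$pixel_size)
        blob <- spec$amplitude *
          outer(exp(-(rows - pc[2])^2 / s2), exp(-(cols - pc[1])^2 / s2))
        arr[, , t] <- arr[, , t] + blob
      }
      if (spec$noise_sd > 0) {
        arr[, , t] <- arr[, , t] + stats::rnorm(h * w, 0, spec$noise_sd)
      }
    }
    pmax(arr, 0)
  })
  image_sequence(frames, pixel_size = spec$pixel_size, dt = dt)
}

#' Binary tumor mask for a rendering spec
#'
#' Pixels whose centre lies within `tumor_radius` of `tumor_center` are
#' `TRUE`. With radius 0 the mask contains the single pixel whose centre
#' coincides with the centre point (empty if the centre falls between pixel
#' centres).
#'
#' @param spec A [render_spec()].
#' @return Logical (height x width) matrix.
#' @export
make_tumor_mask <- function(spec) {
  stopifnot(inherits(spec, "render_spec"))
  h <- spec$image_shape[1]
  w <- spec$image_shape[2]
  cx <- spec$tumor_center[1]
  cy <- spec$tumor_center[2]
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  d2 <= spec$tumor_radius^2
}

#' Write / read a timelapse as multi-page grayscale TIFF
#'
#' Intensities are stored as 32-bit floats scaled to [0, 1] by the recorded
#' `intensity_scale` (the sequence max), so round-trips restore the original
#' values up to float precision.
#'
#' @param seq An [image_sequence()].
#' @param path Output .tif path.
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  scale <- max(seq$frames, 1e-12)
  pages <- lapply(seq_len(dim(seq$frames)[3]), function(t) seq$frames[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size = seq$pixel_size, dt = seq$dt, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timelapse
#' @param pixel_size,dt Metadata used if no sidecar JSON is found.
#' @export
read_timelapse <- function(path, pixel_size = NULL, dt = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scale <- meta$intensity_scale
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size
    if (is.null(dt)) dt <- meta$dt
  }
  if (is.null(pixel_size)) pixel_size <- 1
  if (is.null(dt)) dt <- 60
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    frames[, , t] <- pg * scale
  }
  image_sequence(frames, pixel_size = pixel_size, dt = dt)
}

#' Write / read a binary mask as single-page 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output .tif path.
#' @return `path` invisibly; `read_mask` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}
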