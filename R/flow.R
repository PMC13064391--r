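#' Optical-flow parameters
#'
#' Settings of the dense pyramidal Lucas-Kanade flow estimator.
#'
#' @param pyr_levels Number of pyramid levels (default 3); level 1 is full
#'   resolution, each further level halves the image. More levels extend
#'   the reachable displacement (roughly `win_sigma * 2^(levels-1)` px).
#' @param iters Warping-refinement iterations per level (default 3).
#' @param win_sigma Sigma (px) of the Gaussian window weighting the local
#'   least-squares system (default 3).
#' @param smooth_sigma Pre-smoothing sigma (px) applied to both frames
#'   (default 1).
#' @param min_eig Minimum smaller eigenvalue of the Gaussian-windowed
#'   structure tensor for a pixel to receive a flow update, in units of
#'   squared intensity gradient after the frame pair is rescaled to unit
#'   peak. Pixels below it (textureless, e.g. pure background noise) are
#'   left at zero flow.
#' @return List of class `"flow_params"`.
#' @export
flow_params <- function(pyr_levels = 3L, iters = 3L, win_sigma = 3,
                        smooth_sigma = 1, min_eig = 1e-4) {
  stopifnot(pyr_levels >= 1, iters >= 1, win_sigma > 0)
  structure(
    list(
      pyr_levels = as.integer(pyr_levels), iters = as.integer(iters),
      win_sigma = win_sigma, smooth_sigma = smooth_sigma, min_eig = min_eig
    ),
    class = "flow_params"
  )
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing with replicated borders
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  sep_filter(img, k)
}

sep_filter <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  h <- nrow(img)
  w <- ncol(img)
  # filter along rows (vertical), then columns, replicating the border
  padr <- img[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  tmp <- matrix(0, h, w)
  for (i in seq_along(k)) tmp <- tmp + k[i] * padr[i:(i + h - 1L), , drop = FALSE]
  padc <- tmp[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * padc[, i:(i + w - 1L), drop = FALSE]
  out
}

# central-difference spatial gradients, replicated borders
grad_x <- function(img) {
  w <- ncol(img)
  (img[, c(2:w, w), drop = FALSE] - img[, c(1, 1:(w - 1)), drop = FALSE]) / 2
}
grad_y <- function(img) {
  h <- nrow(img)
  (img[c(2:h, h), , drop = FALSE] - img[c(1, 1:(h - 1)), , drop = FALSE]) / 2
}

pyr_down <- function(img) {
  sm <- gauss_smooth(img, 1)
  sm[seq(1L, nrow(img), by = 2L), seq(1L, ncol(img), by = 2L), drop = FALSE]
}

# bilinear sampling of img at (row + v, col + u), clamped to the frame
warp_bilinear <- function(img, u, v) {
  h <- nrow(img)
  w <- ncol(img)
  rs <- pmin(pmax(row(img) + v, 1), h)
  cs <- pmin(pmax(col(img) + u, 1), w)
  r0 <- floor(rs)
  c0 <- floor(cs)
  r1 <- pmin(r0 + 1, h)
  c1 <- pmin(c0 + 1, w)
  fr <- rs - r0
  fc <- cs - c0
  idx <- function(r, c) r + (c - 1) * h
  out <- (1 - fr) * (1 - fc) * img[idx(r0, c0)] +
    fr * (1 - fc) * img[idx(r1, c0)] +
    (1 - fr) * fc * img[idx(r0, c1)] +
    fr * fc * img[idx(r1, c1)]
  matrix(out, h, w)
}

texture_mask <- function(img, params) {
  k <- gaussian_kernel1d(params$win_sigma)
  ix <- grad_x(img)
  iy <- grad_y(img)
  sxx <- sep_filter(ix * ix, k)
  syy <- sep_filter(iy * iy, k)
  sxy <- sep_filter(ix * iy, k)
  lam_min <- ((sxx + syy) - sqrt((sxx - syy)^2 + 4 * sxy * sxy)) / 2
  lam_min > params$min_eig
}

lk_refine <- function(a, b, u, v, params) {
  k <- gaussian_kernel1d(params$win_sigma)
  for (it in seq_len(params$iters)) {
    bw <- warp_bilinear(b, u, v)
    im <- (a + bw) / 2
    ix <- grad_x(im)
    iy <- grad_y(im)
    it_ <- bw - a
    sxx <- sep_filter(ix * ix, k)
    syy <- sep_filter(iy * iy, k)
    sxy <- sep_filter(ix * iy, k)
    sxt <- sep_filter(ix * it_, k)
    syt <- sep_filter(iy * it_, k)
    det <- sxx * syy - sxy * sxy
    # smaller eigenvalue of the structure tensor: texture in the weaker axis
    lam_min <- ((sxx + syy) - sqrt((sxx - syy)^2 + 4 * sxy * sxy)) / 2
    ok <- lam_min > params$min_eig & det > 0
    du <- matrix(0, nrow(a), ncol(a))
    dv <- du
    du[ok] <- (-sxt[ok] * syy[ok] + syt[ok] * sxy[ok]) / det[ok]
    dv[ok] <- (-syt[ok] * sxx[ok] + sxt[ok] * sxy[ok]) / det[ok]
    u <- u + du
    v <- v + dv
  }
  list(u = u, v = v)
}

#' Dense optical flow between two frames
#'
#' Estimates the per-pixel apparent motion from `frame_a` to `frame_b`
#' (px/frame) with a pyramidal, iteratively warped Lucas-Kanade scheme:
#' local constant-flow least squares in a Gaussian window, refined
#' coarse-to-fine so translations of several pixels are recovered.
#' Textureless pixels (degenerate normal matrix) are assigned zero flow;
#' identical frames yield an all-zero field.
#'
#' @param frame_a,frame_b Numeric matrices of the same shape.
#' @param params A [flow_params()] list.
#' @return List of class `"flow_field"` with matrices `u` (x/column
#'   displacement) and `v` (y/row displacement) in px/frame.
#' @export
estimate_flow <- function(frame_a, frame_b, params = flow_params()) {
  if (!all(dim(frame_a) == dim(frame_b))) {
    stop("frames must have the same shape", call. = FALSE)
  }
  # flow is invariant to a common intensity rescaling; normalizing to unit
  # peak makes the min_eig texture threshold scale-free
  scale <- max(abs(frame_a), abs(frame_b), 1e-12)
  a <- gauss_smooth(frame_a / scale, params$smooth_sigma)
  b <- gauss_smooth(frame_b / scale, params$smooth_sigma)
  pyr_a <- list(a)
  pyr_b <- list(b)
  lv <- 1L
  while (lv < params$pyr_levels && min(dim(pyr_a[[lv]])) >= 16L) {
    pyr_a[[lv + 1L]] <- pyr_down(pyr_a[[lv]])
    pyr_b[[lv + 1L]] <- pyr_down(pyr_b[[lv]])
    lv <- lv + 1L
  }
  u <- matrix(0, nrow(pyr_a[[lv]]), ncol(pyr_a[[lv]]))
  v <- u
  for (level in rev(seq_len(lv))) {
    if (level < lv) {
      # upsample flow to this level's grid and double the magnitudes
      hh <- nrow(pyr_a[[level]])
      ww <- ncol(pyr_a[[level]])
      u <- upsample2(u, hh, ww) * 2
      v <- upsample2(v, hh, ww) * 2
    }
    fl <- lk_refine(pyr_a[[level]], pyr_b[[level]], u, v, params)
    u <- fl$u
    v <- fl$v
  }
  # coarse levels propagate estimates into textureless regions; keep flow
  # only where the full-resolution image carries enough texture
  ok <- texture_mask(a, params)
  u[!ok] <- 0
  v[!ok] <- 0
  structure(list(u = u, v = v), class = "flow_field")
}

upsample2 <- function(m, h, w) {
  ri <- pmin(pmax(ceiling(seq_len(h) / 2), 1), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(w) / 2), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf(
    "<flow_field> %dx%d px, median |v| = %.3f px/frame\n",
    nrow(x$u), ncol(x$u), stats::median(mag)
  ))
  invisible(x)
}

#' Time-averaged pixel-motility map
#'
#' Computes dense optical flow for every consecutive frame pair of a
#' timelapse, averages the per-pixel flow magnitude over the pairs, and
#' min-max rescales the result to [0, 1] ([mat2gray()] semantics). High
#' values mark pixels where the fluorescence signal moved throughout the
#' recording. A constant raw map (e.g. from a static sequence) maps to all
#' zeros and is flagged.
#'
#' @param seq An [image_sequence()] with at least 2 frames.
#' @param params A [flow_params()] list.
#' @param stat Temporal statistic over frame pairs: `"mean"` (default) or
#'   `"max"`.
#' @return Object of class `"motility_map"`: list with `values` (H x W in
#'   [0,1]), `raw` (unnormalized mean magnitudes, px/frame), `range`
#'   (normalization min/max), `constant` flag, `pixel_size`, `dt`.
#' @export
motility_map <- function(seq, params = flow_params(), stat = c("mean", "max")) {
  stopifnot(inherits(seq, "image_sequence"))
  stat <- match.arg(stat)
  d <- dim(seq$frames)
  if (d[3] < 2) stop("need at least 2 frames", call. = FALSE)
  acc <- matrix(0, d[1], d[2])
  for (t in seq_len(d[3] - 1L)) {
    fl <- estimate_flow(seq$frames[, , t], seq$frames[, , t + 1L], params)
    mag <- sqrt(fl$u^2 + fl$v^2)
    acc <- if (stat == "mean") acc + mag else pmax(acc, mag)
  }
  if (stat == "mean") acc <- acc / (d[3] - 1L)
  values <- mat2gray(acc)
  constant <- attr(values, "constant")
  attr(values, "constant") <- NULL
  structure(
    list(
      values = values, raw = acc, range = range(acc), constant = constant,
      pixel_size = seq$pixel_size, dt = seq$dt
    ),
    class = "motility_map"
  )
}

#' @export
print.motility_map <- function(x, ...) {
  cat(sprintf(
    "<motility_map> %dx%d px, raw range [%.4g, %.4g]%s\n",
    nrow(x$values), ncol(x$values), x$range[1], x$range[2],
    if (x$constant) " (constant)" else ""
  ))
  invisible(x)
}
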