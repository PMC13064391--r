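#' Concentric erosion bands of a tumor mask
#'
#' Progressively erodes the tumor region of interest to resolve position
#' relative to the tumor border: `E_0` is the mask, `E_(i+1)` erodes `E_i`
#' by a Euclidean disk of radius `spacing_px` (computed by thresholding the
#' Euclidean distance transform, which gives exact isotropic "equidistant"
#' semantics), and band `i` is `E_i` minus `E_(i+1)`. Erosion stops when it
#' empties the mask; the last non-empty `E` is the innermost core. Bands
#' are labelled with Roman numerals from peripheral (I) to deep.
#'
#' @param mask Logical (or 0/1) matrix; non-empty.
#' @param spacing_um Band spacing in micrometers (default 40).
#' @param pixel_size Pixel size, um/px; `round(spacing_um / pixel_size)`
#'   must be at least 1 px.
#' @return Object of class `"roi_bands"`: list with `source_mask`,
#'   `spacing_px`, `bands` (list of disjoint logical masks whose union is
#'   the source mask), `labels`.
#' @export
erode_bands <- function(mask, spacing_um = 40, pixel_size = 1) {
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  spacing_px <- round(spacing_um / pixel_size)
  if (spacing_px < 1) {
    stop("band spacing is below one pixel; decrease pixel_size or increase spacing",
      call. = FALSE
    )
  }
  # distance (px) of each foreground pixel to the nearest background pixel
  dm <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
  dm <- as.matrix(EBImage::imageData(dm))
  bands <- list()
  i <- 0L
  repeat {
    e_cur <- mask & dm > i * spacing_px
    e_next <- mask & dm > (i + 1L) * spacing_px
    if (!any(e_next)) {
      bands[[i + 1L]] <- e_cur # innermost core
      break
    }
    bands[[i + 1L]] <- e_cur & !e_next
    i <- i + 1L
  }
  structure(
    list(
      source_mask = mask, spacing_px = spacing_px, bands = bands,
      labels = as.character(utils::as.roman(seq_along(bands)))
    ),
    class = "roi_bands"
  )
}

#' @export
print.roi_bands <- function(x, ...) {
  cat(sprintf(
    "<roi_bands> %d regions (spacing %d px): %s\n",
    length(x$bands), x$spacing_px,
    paste(sprintf("%s=%dpx", x$labels, vapply(x$bands, sum, integer(1))),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Mean motility per erosion band
#'
#' @param map A [motility_map()] (or plain numeric matrix).
#' @param bands A [erode_bands()] result sharing the map's shape.
#' @return Data frame with `region` (Roman numeral, peripheral to deep),
#'   `pixel_count`, and `mean` motility; a zero-pixel band gets mean NA and
#'   is flagged with a warning.
#' @export
band_motility <- function(map, bands) {
  values <- if (inherits(map, "motility_map")) map$values else map
  stopifnot(inherits(bands, "roi_bands"))
  if (!all(dim(values) == dim(bands$source_mask))) {
    stop("map and bands have different shapes", call. = FALSE)
  }
  counts <- vapply(bands$bands, sum, integer(1))
  means <- vapply(seq_along(bands$bands), function(i) {
    if (counts[i] == 0) NA_real_ else mean(values[bands$bands[[i]]])
  }, numeric(1))
  if (any(counts == 0)) warning("zero-pixel band: mean undefined")
  data.frame(
    region = bands$labels, pixel_count = counts, mean = means,
    stringsAsFactors = FALSE
  )
}

#' Paired band motility before and after treatment
#'
#' Runs [motility_map()] and [band_motility()] on the pre- and
#' post-treatment sequences with one shared band decomposition of the tumor
#' mask, producing the paired per-band table used to assess motility
#' polarization from the tumor periphery toward the core.
#'
#' @param seq_pre,seq_post [image_sequence()] objects sharing geometry with
#'   `mask`.
#' @param mask Tumor mask (logical matrix).
#' @param spacing_um Band spacing, um.
#' @param params [flow_params()].
#' @return Data frame with `region`, `pixel_count`, `mean_pre`, `mean_post`.
#' @export
before_after_bands <- function(seq_pre, seq_post, mask, spacing_um = 40,
                               params = flow_params()) {
  stopifnot(inherits(seq_pre, "image_sequence"), inherits(seq_post, "image_sequence"))
  if (!all(dim(seq_pre$frames)[1:2] == dim(mask)) ||
    !all(dim(seq_post$frames)[1:2] == dim(mask)) ||
    seq_pre$pixel_size != seq_post$pixel_size) {
    stop("sequences and mask must share geometry", call. = FALSE)
  }
  bands <- erode_bands(mask, spacing_um = spacing_um, pixel_size = seq_pre$pixel_size)
  pre <- band_motility(motility_map(seq_pre, params), bands)
  post <- band_motility(motility_map(seq_post, params), bands)
  data.frame(
    region = pre$region, pixel_count = pre$pixel_count,
    mean_pre = pre$mean, mean_post = post$mean,
    stringsAsFactors = FALSE
  )
}
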