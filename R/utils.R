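#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that every generator in the package is a pure function of
#' its (params, seed) arguments and never disturbs the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and an index
#'
#' Splitting scheme for per-track seeds: deterministic, collision-free for
#' indices below the multiplier, and kept inside the 32-bit integer range.
#'
#' @param seed Parent integer seed.
#' @param index Positive integer index.
#' @return Integer child seed in [0, 2^31 - 1).
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647)
}

#' Min-max rescale to the unit interval
#'
#' mat2gray-style normalization: `(x - min) / (max - min)`. A constant input
#' maps to all zeros (degenerate case), signalled via the `"constant"`
#' attribute.
#'
#' @param x Numeric array.
#' @return Array of the same shape with values in [0, 1]; attribute
#'   `"constant"` is `TRUE` when the input had zero range.
#' @export
mat2gray <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    out <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (x - lo) / (hi - lo)
  attr(out, "constant") <- FALSE
  out
}

log_stage <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
}
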