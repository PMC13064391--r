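ARCHETYPE_NAMES <- c(
  "flowing", "directed", "patrolling", "focused_patrolling", "arrested"
)

#' Archetype simulation parameters
#'
#' Parameter set for the two-state (move/pause) persistent-random-walk
#' generator behind one behavioral archetype.
#'
#' @param name Archetype name; one of `"flowing"`, `"directed"`,
#'   `"patrolling"`, `"focused_patrolling"`, `"arrested"`.
#' @param speed_mean,speed_sd Mean and SD of the instantaneous speed while
#'   moving, um/min. Negative draws are truncated at 0.
#' @param persistence Directional persistence in [0, 1]: the expected cosine
#'   of the per-step turning angle. 1 is ballistic motion, 0 a memoryless
#'   random walk. Turning angles are wrapped-normal with
#'   `sigma = sqrt(-2 * log(persistence))`.
#' @param pause_on_prob,pause_off_prob Per-step probabilities of entering and
#'   leaving the paused state of the two-state Markov chain.
#' @param target_bias Weight in [0, 1] of the drift toward `target`; 0 for
#'   all archetypes except `directed`.
#' @param n_steps Number of positions (frames) per track; at least 2.
#' @param dt Frame interval, seconds.
#' @param z_jitter_sd SD of the per-step z displacement, um. Kept well below
#'   the in-plane step so that tracks are effectively planar, matching the
#'   2-D rendering and flow analysis.
#' @return An object of class `"archetype_params"`.
#' @export
archetype_params <- function(name, speed_mean, speed_sd, persistence,
                             pause_on_prob, pause_off_prob,
                             target_bias = 0, n_steps = 40L, dt = 60,
                             z_jitter_sd = 0.1) {
  name <- match.arg(name, ARCHETYPE_NAMES)
  probs <- c(
    persistence = persistence, pause_on_prob = pause_on_prob,
    pause_off_prob = pause_off_prob, target_bias = target_bias
  )
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("persistence, pause probabilities and target_bias must lie in [0, 1]",
      call. = FALSE
    )
  }
  if (!is.finite(speed_mean) || speed_mean < 0) {
    stop("`speed_mean` must be >= 0", call. = FALSE)
  }
  if (!is.finite(speed_sd) || speed_sd < 0) {
    stop("`speed_sd` must be >= 0", call. = FALSE)
  }
  if (n_steps < 2) stop("`n_steps` must be >= 2", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  structure(
    list(
      name = name, speed_mean = speed_mean, speed_sd = speed_sd,
      persistence = persistence, pause_on_prob = pause_on_prob,
      pause_off_prob = pause_off_prob, target_bias = target_bias,
      n_steps = as.integer(n_steps), dt = dt, z_jitter_sd = z_jitter_sd
    ),
    class = "archetype_params"
  )
}

#' Default archetype presets
#'
#' The five behavioral archetypes used as ground truth by the synthetic
#' cohort generator: flowing (fast, persistent), directed (fast,
#' target-biased), patrolling (moderate speed, frequent turning),
#' focused patrolling (slow, often paused) and arrested (essentially
#' stationary). The constants are fixed package defaults chosen so that the
#' archetypes are well separated in speed, displacement and pausing; they
#' claim no correspondence to any in vivo measurement.
#'
#' Mean moving speeds are strictly ordered
#' flowing > directed > patrolling > focused_patrolling > arrested, and
#' stationary pause fractions `pause_on / (pause_on + pause_off)` are
#' ordered arrested > focused_patrolling > the rest.
#'
#' @param n_steps Frames per track (default 40).
#' @param dt Frame interval, seconds (default 60; five timeframes then equal
#'   300 s, the duration-filter cutoff).
#' @return Named list of five [archetype_params()] objects.
#' @export
archetype_presets <- function(n_steps = 40L, dt = 60) {
  list(
    flowing = archetype_params(
      "flowing",
      speed_mean = 16, speed_sd = 2.5, persistence = 0.95,
      pause_on_prob = 0.01, pause_off_prob = 0.9,
      n_steps = n_steps, dt = dt
    ),
    directed = archetype_params(
      "directed",
      speed_mean = 9, speed_sd = 2, persistence = 0.9,
      pause_on_prob = 0.04, pause_off_prob = 0.8, target_bias = 0.6,
      n_steps = n_steps, dt = dt
    ),
    patrolling = archetype_params(
      "patrolling",
      speed_mean = 5, speed_sd = 1.5, persistence = 0.3,
      pause_on_prob = 0.12, pause_off_prob = 0.6,
      n_steps = n_steps, dt = dt
    ),
    focused_patrolling = archetype_params(
      "focused_patrolling",
      speed_mean = 2.5, speed_sd = 0.8, persistence = 0.15,
      pause_on_prob = 0.35, pause_off_prob = 0.35,
      n_steps = n_steps, dt = dt
    ),
    arrested = archetype_params(
      "arrested",
      speed_mean = 0.8, speed_sd = 0.3, persistence = 0.05,
      pause_on_prob = 0.7, pause_off_prob = 0.12,
      n_steps = n_steps, dt = dt
    )
  )
}
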