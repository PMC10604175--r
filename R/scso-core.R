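#' Sensitivity schedule of the sand cat swarm
#'
#' The general sensitivity `rg` mimics the sand cat's hearing range: it starts
#' at `sM` (2 kHz by default) and decays linearly to 0 over the run, shifting
#' the swarm from exploration toward exploitation.
#'
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Maximum number of iterations, positive.
#' @param sM Initial sensitivity, positive. Default 2.
#' @return `sM - sM * t / t_max`, a value in `[0, sM]`.
#' @examples
#' compute_rg(0, 50)   # 2
#' compute_rg(25, 50)  # 1
#' compute_rg(50, 50)  # 0
#' @export
compute_rg <- function(t, t_max, sM = 2) {
  if (length(t_max) != 1L || t_max <= 0) {
    stop("invalid schedule: `t_max` must be a positive integer", call. = FALSE)
  }
  if (any(t < 0) || any(t > t_max)) {
    stop("invalid schedule: `t` must lie in [0, t_max]", call. = FALSE)
  }
  if (sM <= 0) stop("`sM` must be positive", call. = FALSE)
  sM - sM * t / t_max
}

#' Phase-control value R
#'
#' Maps a uniform draw onto `[-rg, rg]`; the sign and magnitude of R decide
#' whether an agent exploits (moves toward the best solution) or explores.
#'
#' @param rg General sensitivity, non-negative.
#' @param u Uniform draw in \\[0, 1\\]; defaults to a fresh draw.
#' @return `2 * rg * u - rg`.
#' @export
compute_R <- function(rg, u = stats::runif(1)) {
  stopifnot(rg >= 0, u >= 0, u <= 1)
  2 * rg * u - rg
}

#' Per-agent sensitivity r
#'
#' @param rg General sensitivity, non-negative.
#' @param u Uniform draw in \\[0, 1\\]; defaults to a fresh draw.
#' @return `rg * u`, in `[0, rg]`.
#' @export
compute_r <- function(rg, u = stats::runif(1)) {
  stopifnot(rg >= 0, u >= 0, u <= 1)
  rg * u
}

#' Random movement angle
#'
#' Each position update moves along a random angle; the roulette wheel over
#' equal slices degenerates to a uniform draw over \\[0, 360\\] degrees.
#'
#' @param n Number of angles to draw.
#' @return Numeric vector of angles in degrees.
#' @export
sample_theta <- function(n = 1) {
  stats::runif(n, 0, 360)
}

#' Exploitation update (attacking the prey)
#'
#' Computes the distance term `Xrand = |u1 * xbest - x|` and steps from the
#' best position against that distance along the cosine of the movement angle.
#' All arguments recycle, so one call updates a whole dimension vector.
#'
#' @param x Current position component(s).
#' @param xbest Best position component(s).
#' @param u1,u2 Uniform draws in \\[0, 1\\].
#' @param theta_deg Movement angle(s) in degrees.
#' @param use_abs Take the magnitude of the distance term (default). `FALSE`
#'   gives the strict-literal signed variant.
#' @return Updated continuous position component(s).
#' @examples
#' exploit_update(0, 1, u1 = 0.5, u2 = 1, theta_deg = 180)  # 1.5
#' @export
exploit_update <- function(x, xbest, u1, u2, theta_deg, use_abs = TRUE) {
  xrand <- u1 * xbest - x
  if (use_abs) xrand <- abs(xrand)
  xbest - u2 * xrand * cos(theta_deg * pi / 180)
}

#' Exploration update (searching for prey)
#'
#' @param x Current position component(s).
#' @param xcand Candidate (random peer) position component(s).
#' @param r Per-agent sensitivity, non-negative.
#' @param u Uniform draw(s) in \\[0, 1\\].
#' @return `r * (xcand - u * x)`.
#' @export
explore_update <- function(x, xcand, r, u) {
  stopifnot(all(r >= 0))
  r * (xcand - u * x)
}

#' Pick a random candidate individual
#'
#' Index `floor(N * u) + 1`, uniform over the population (1-based).
#'
#' @param n_pop Population size, positive.
#' @param u Uniform draw(s) in \\[0, 1\\); defaults to fresh draws.
#' @return Integer index (or vector of indices) in `1..n_pop`.
#' @export
pick_candidate <- function(n_pop, u = stats::runif(1)) {
  if (length(n_pop) != 1L || n_pop < 1) {
    stop("population must be non-empty", call. = FALSE)
  }
  pmin(as.integer(floor(n_pop * u) + 1), as.integer(n_pop))
}
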