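#' Single-point crossover of two bit vectors
#'
#' Swaps all bits after the cut point between the two parents, yielding two
#' offspring. Position-wise, each offspring pair conserves the parents' bits.
#'
#' @param p1,p2 Integer bit vectors of the same length `D >= 2`.
#' @param cut Cut position in `1..(D-1)`; bits at indices greater than `cut`
#'   are swapped. Defaults to a uniform draw over the valid positions.
#' @return List of two offspring bit vectors `q1`, `q2`.
#' @examples
#' single_point_crossover(c(1, 1, 1, 1), c(0, 0, 0, 0), cut = 2)
#' @export
single_point_crossover <- function(p1, p2,
                                   cut = sample.int(length(p1) - 1L, 1L)) {
  d <- length(p1)
  if (length(p2) != d) stop("parents must have equal length", call. = FALSE)
  if (d < 2L) stop("parents must have length >= 2", call. = FALSE)
  if (length(cut) != 1L || cut < 1L || cut > d - 1L) {
    stop("`cut` must lie in 1..(D-1)", call. = FALSE)
  }
  head_idx <- seq_len(cut)
  q1 <- c(p1[head_idx], p2[-head_idx])
  q2 <- c(p2[head_idx], p1[-head_idx])
  list(q1 = as.integer(q1), q2 = as.integer(q2))
}

#' Pinhole-imaging reverse of a position
#'
#' The pinhole-imaging construction projects the current position through a
#' small aperture onto the opposite side of the search interval `[a, b]`:
#' the reverse point is `(a + b)/2 + (a + b)/(2 K) - x / K`, where `K` is the
#' ratio of the object and image heights. The interval midpoint is the fixed
#' point; small `K` throws the image far beyond the opposite bound, which is
#' what gives the operator its exploratory reach.
#'
#' @param x Position value(s).
#' @param a,b Lower and upper bounds of the dimension (`a < b`); 0 and 1 in
#'   binary feature space.
#' @param K Scale factor, positive. Default 0.05.
#' @return The reversed position value(s).
#' @examples
#' pinhole_reverse(1)  # -9.5
#' pinhole_reverse(0)  # 10.5
#' @export
pinhole_reverse <- function(x, a = 0, b = 1, K = 0.05) {
  if (length(K) != 1L || K == 0) stop("`K` must be non-zero", call. = FALSE)
  if (K < 0) stop("`K` must be positive", call. = FALSE)
  if (any(a >= b)) stop("bounds must satisfy a < b", call. = FALSE)
  (a + b) / 2 + (a + b) / (2 * K) - x / K
}

#' Pinhole-imaging opposition candidate for a bit vector
#'
#' Applies the pinhole reverse per dimension in binary bounds `[0, 1]`,
#' re-binarizes the reversed value at `threshold` (at the default `K = 0.05`
#' the reverse of a bit is -9.5 or 10.5, so this is exactly the bitwise
#' complement of `x`), and masks the result with the current best solution
#' via a bitwise AND. The candidate is therefore always a subset of `xbest`:
#' opposition can only drop genes that the best solution carries, never add
#' genes it lacks.
#'
#' @param x Current individual's bit vector.
#' @param xbest Global best bit vector, same length.
#' @param K Pinhole scale factor. Default 0.05.
#' @param threshold Re-binarization threshold on the reversed value; values
#'   `>= threshold` map to 1. Default 0.5.
#' @return Integer bit vector, a subset of `xbest`.
#' @export
piobl_candidate <- function(x, xbest, K = 0.05, threshold = 0.5) {
  if (length(x) != length(xbest)) {
    stop("`x` and `xbest` must have equal length", call. = FALSE)
  }
  rev_val <- pinhole_reverse(x, a = 0, b = 1, K = K)
  q1 <- as.integer(rev_val >= threshold)
  as.integer(q1 & xbest)
}
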