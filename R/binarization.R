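#' Tansig transfer function
#'
#' Maps a continuous position update onto `(-1, 1)` through the hyperbolic
#' tangent sigmoid `2 / (1 + exp(-2 v)) - 1`, which is algebraically identical
#' to `tanh(v)`. The transferred value acts as a probability-like score for
#' setting the corresponding feature bit.
#'
#' @param v Finite numeric vector of continuous positions.
#' @return Transferred values, strictly inside `(-1, 1)`, monotone in `v`.
#' @examples
#' transfer_tansig(0)       # 0
#' transfer_tansig(10)      # ~1
#' @export
transfer_tansig <- function(v) {
  if (any(!is.finite(v))) {
    stop("`v` must be finite", call. = FALSE)
  }
  2 / (1 + exp(-2 * v)) - 1
}

#' Stochastic binarization of a transferred value
#'
#' Emits 1 exactly when the transferred value strictly exceeds a uniform
#' draw. Because the draw is non-negative, non-positive transferred values
#' always binarize to 0: under the tansig scheme a bit can only switch on
#' through a positive continuous update.
#'
#' @param tf Transferred value(s) in `(-1, 1)`.
#' @param u Uniform draw(s) in \\[0, 1\\]; defaults to fresh draws, one per
#'   element of `tf`.
#' @return Integer bit vector: `1L` where `tf > u`, else `0L`.
#' @export
binarize <- function(tf, u = stats::runif(length(tf))) {
  as.integer(tf > u)
}
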