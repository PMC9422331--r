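#' Circular disparity between two directions
#'
#' Shortest angular distance between two directions on the circle, in degrees.
#' This is the disparity measure used throughout: between unisensory preferred
#' directions (`dtheta_uni`), between the two members of the multisensory
#' preferred pair (`dtheta_mul`), and between response-bump centres.
#'
#' @param theta_a,theta_b Directions in degrees (any real values; reduced
#'   modulo 360). Vectorised and recycled.
#' @return Disparities in degrees, in `[0, 180]`.
#' @examples
#' circular_disparity(10, 350)  # 20
#' circular_disparity(0, 180)   # 180
#' @export
circular_disparity <- function(theta_a, theta_b) {
  x <- abs(theta_a - theta_b) %% 360
  ifelse(x > 180, 360 - x, x)
}

# stimulus direction grid of the recording protocol (8 directions, 45 deg apart)
directions8 <- seq(0, 315, by = 45)

# disparity support on the 45-degree grid
disparity_bins <- seq(0, 180, by = 45)

# circular-Gaussian tuning profile on disparity d (degrees), unit peak
circ_gauss <- function(d, width) exp(-d^2 / (2 * width^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seeds derived from one user seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a finite numeric scalar", call. = FALSE)
  invisible(x)
}
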