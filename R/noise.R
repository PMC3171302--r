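#' Additive Gaussian measurement noise for RNA count series
#'
#' Emulates measurement error in single-molecule RNA counting: each sampled
#' value receives an independent Gaussian(0, `sd`) addend, and any value
#' that comes out negative is set to exactly 0.
#'
#' @param series Integer series (vector or matrix, one row per cell).
#' @param sd Noise standard deviation (default 0.5).
#' @param seed Optional seed for the noise draws.
#' @return Real-valued series of the same shape.
#' @examples
#' add_measurement_noise(matrix(10L, 2, 5), sd = 0.5, seed = 1)
#' @export
add_measurement_noise <- function(series, sd = 0.5, seed = NULL) {
  if (sd < 0) stop("noise sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  out <- series + stats::rnorm(length(series), 0, sd)
  out[out < 0] <- 0
  out
}

#' Map real-valued (noisy) observations back to integer states
#'
#' The integer-state Markov chain is evaluated on noisy data by rounding
#' each nonnegative observation to the nearest integer (half away from
#' zero), which is unbiased for symmetric noise.
#'
#' @param series Nonnegative real-valued series (vector or matrix).
#' @return Integer series of the same shape.
#' @examples
#' discretize_observations(c(0.4, 0.5, 1.49)) # 0 1 1
#' @export
discretize_observations <- function(series) {
  if (any(series < 0)) stop("observations must be nonnegative")
  out <- floor(series + 0.5)
  storage.mode(out) <- "integer"
  out
}
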