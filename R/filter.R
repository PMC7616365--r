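#' Kalman-Bucy gain of the motor-preparation filter
#'
#' Time-varying gain `lambda' * tanh(lambda' * t)` that optimally weights
#' the innovation when recovering a drifting diffusion observed in white
#' noise. The gain rises from 0 at `t = 0` to its asymptote `lambda'`
#' within a few multiples of `1 / lambda'`; the constant-leak filter is the
#' steady-state approximation.
#'
#' @param lambda_prime gain prior / asymptote (1/s, >= 0).
#' @param t time(s) since accumulation onset (s, >= 0). Vectorized.
#' @return gain value(s), 1/s; nondecreasing in `t` and bounded by
#'   `lambda_prime`.
#' @export
kalman_gain <- function(lambda_prime, t) {
  if (any(!is.finite(lambda_prime)) || any(lambda_prime < 0))
    stop("`lambda_prime` must be finite and >= 0")
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0")
  lambda_prime * tanh(lambda_prime * t)
}

#' Closed-form mean of the filtered motor-preparation variable
#'
#' Expected value of the leaky filter output `y(t)` when the decision
#' stage has mean path `x0 + v t` and both stages start at `x0`:
#' `E[y(t)] = x0 + v * (t - (1 - exp(-lambda t)) / lambda)`.
#' For `t >> 1/lambda` this is `x0 + v * (t - 1/lambda)`: the filter delays
#' the mean drift by `1/lambda` seconds.
#'
#' @param v mean drift rate (evidence-units/s).
#' @param lambda leak (1/s, > 0).
#' @param t time(s) since onset (s, >= 0). Vectorized.
#' @param x0 shared starting point (evidence units).
#' @return expected `y(t)` (evidence units).
#' @export
mean_filter_trajectory <- function(v, lambda, t, x0 = 0) {
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be > 0")
  if (any(t < 0)) stop("`t` must be >= 0")
  x0 + v * (t - (1 - exp(-lambda * t)) / lambda)
}
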