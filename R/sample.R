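#' Draw the realized parameters of one trial
#'
#' Samples the trial-level parameter values from the between-trial
#' variability distributions: drift Normal(`v`, `sv`); starting point,
#' residual latencies and leak Uniform with the stated means and ranges.
#' With all variability terms zero the realized values equal the means
#' exactly and no random draws are consumed. Draws come from R's global
#' RNG, in the fixed order drift, starting point, Te, Tr, leak, so that a
#' seed fully determines the trial.
#'
#' @param params a validated [gcdf_params()] object.
#' @param map a [drift_maps] object.
#' @param condition condition label (or numeric value for the linear /
#'   criterion forms).
#' @param value numeric condition value when it differs from the label.
#' @return an object of class `gcdf_trial_params`: list with elements
#'   `v`, `x0`, `Te`, `Tr`, `lambda` (the latter `Inf` for `GCD`).
#' @export
sample_trial_params <- function(params, map, condition, value = condition) {
  m <- condition_moments(params, map, condition, value)
  v_trial <- stats::rnorm(1, m$v, m$sv)
  x0_trial <- stats::runif(1, params$x0 - params$sx0 / 2,
                              params$x0 + params$sx0 / 2)
  Te_trial <- stats::runif(1, m$Te - params$sTe / 2, m$Te + params$sTe / 2)
  Tr_trial <- stats::runif(1, params$Tr - params$sTr / 2,
                              params$Tr + params$sTr / 2)
  lambda_trial <- if (params$variant == "GCD" || !is.finite(params$lambda))
    Inf else
    stats::runif(1, params$lambda - params$slambda / 2,
                    params$lambda + params$slambda / 2)
  structure(list(v = v_trial, x0 = x0_trial, Te = Te_trial, Tr = Tr_trial,
                 lambda = lambda_trial),
            class = "gcdf_trial_params")
}
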