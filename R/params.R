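#' Model parameters for a gated cascade diffusion model
#'
#' Container for all parameters of one model variant. The `GCD` variant has
#' no motor-preparation filter (formally an infinite leak, represented here
#' by `lambda = NULL`); `GCDF` adds a leaky first-order filter with leak
#' `lambda` between the decision variable and the gate; `GCDF_KB` further
#' replaces the constant gain by the time-varying Kalman-Bucy gain
#' `lambda * tanh(lambda * t)` and adds white observation noise of scale
#' `xi` on the input to motor preparation.
#'
#' All parameters are in evidence units and seconds. The diffusion
#' coefficient `sigma` is fixed at 0.1 by convention: the model is invariant
#' under a common rescaling of all evidence-unit quantities, so `sigma`
#' merely sets the measurement scale. Pass `sigma_free = TRUE` to override
#' (used for noise-free closed-form checks).
#'
#' Between-trial variability follows the conventions of standard diffusion
#' model applications: the trial drift is Normal with mean `v` and standard
#' deviation `sv`; starting point, residual latencies and leak are Uniform
#' with means `x0`, `Te`, `Tr`, `lambda` and ranges `sx0`, `sTe`, `sTr`,
#' `slambda`. The ranges of `sx0`, `sTe`, `sTr`, `slambda` may not exceed
#' 180% of `g`, `Te`, `Tr`, `lambda` respectively, which also guarantees
#' that realized `Te`, `Tr` and `lambda` stay positive.
#'
#' @param variant one of `"GCD"`, `"GCDF"`, `"GCDF_KB"`.
#' @param g gating inhibition (evidence units, >= 0).
#' @param r response threshold on the neural drive (evidence units, >= 0).
#' @param Te mean residual latency added to the premotor time (s). May be a
#'   named per-condition vector when the drift map carries per-condition
#'   residual latencies (see [drift_conditions()]); validation then applies
#'   to each element.
#' @param Tr mean residual latency added to the motor time (s).
#' @param x0 starting point of evidence accumulation (signed, evidence units).
#' @param lambda leak / gain prior (1/s); `NULL` for the `GCD` variant.
#' @param xi transmission-noise scale (`GCDF_KB` only).
#' @param sigma diffusion coefficient; fixed at 0.1 unless `sigma_free`.
#' @param sv between-trial SD of drift rate; a scalar here, per-condition
#'   values are carried by the drift map.
#' @param sx0,sTe,sTr,slambda between-trial Uniform ranges.
#' @param sigma_free set `TRUE` to permit `sigma != 0.1` (test modes).
#'
#' @return an object of class `gcdf_params` (validated).
#' @seealso [validate_params()], [sample_trial_params()], [drift_linear()]
#' @export
gcdf_params <- function(variant = c("GCDF", "GCD", "GCDF_KB"),
                        g, r, Te, Tr, x0 = 0,
                        lambda = NULL, xi = NULL,
                        sigma = 0.1,
                        sv = 0, sx0 = 0, sTe = 0, sTr = 0, slambda = 0,
                        sigma_free = FALSE) {
  variant <- match.arg(variant)
  p <- structure(list(
    variant = variant,
    sigma = sigma, g = g, r = r, Te = Te, Tr = Tr, x0 = x0,
    lambda = if (variant == "GCD") NULL else lambda,
    xi = if (variant == "GCDF_KB") xi else NULL,
    sv = sv, sx0 = sx0, sTe = sTe, sTr = sTr,
    slambda = if (variant == "GCD") 0 else slambda,
    sigma_free = isTRUE(sigma_free)
  ), class = "gcdf_params")
  validate_params(p)
}

#' Validate model parameters
#'
#' Checks the parameter invariants: nonnegativity of every parameter except
#' the signed starting point `x0`, the 180% caps on the Uniform variability
#' ranges (`sx0 <= 1.8 g`, `sTe <= 1.8 Te`, `sTr <= 1.8 Tr`,
#' `slambda <= 1.8 lambda`), the fixed diffusion coefficient, and
#' variant-specific requirements (`lambda` present and positive for the
#' filtered variants, `xi` for the Kalman-Bucy variant).
#'
#' @param params a `gcdf_params` object.
#' @return `params`, unchanged, if all invariants hold; otherwise an error
#'   naming the offending field and bound.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "gcdf_params"))
  p <- params
  chk_nonneg <- function(val, name) {
    if (is.null(val)) return(invisible())
    if (any(!is.finite(val)) || any(val < 0))
      stop(sprintf("parameter `%s` must be finite and >= 0 (got %s)",
                   name, paste(format(val), collapse = ", ")), call. = FALSE)
  }
  chk_nonneg(p$g, "g"); chk_nonneg(p$r, "r")
  chk_nonneg(p$Te, "Te"); chk_nonneg(p$Tr, "Tr")
  chk_nonneg(p$sv, "sv"); chk_nonneg(p$sx0, "sx0")
  chk_nonneg(p$sTe, "sTe"); chk_nonneg(p$sTr, "sTr")
  chk_nonneg(p$slambda, "slambda")
  if (!is.finite(p$x0)) stop("parameter `x0` must be finite", call. = FALSE)
  if (!p$sigma_free && !isTRUE(all.equal(p$sigma, 0.1)))
    stop("`sigma` is fixed at 0.1 (scaling convention); ",
         "use sigma_free = TRUE to override", call. = FALSE)
  if (p$sigma < 0) stop("parameter `sigma` must be >= 0", call. = FALSE)
  if (p$variant %in% c("GCDF", "GCDF_KB")) {
    if (is.null(p$lambda) || is.na(p$lambda) || p$lambda <= 0)
      stop("variant ", p$variant,
           " requires `lambda` > 0 (1/s); `lambda = Inf` disables the ",
           "filter exactly (the GCD limit)", call. = FALSE)
    if (is.infinite(p$lambda) && p$slambda > 0)
      stop("`slambda` must be 0 when `lambda = Inf`", call. = FALSE)
    if (p$slambda > 1.8 * p$lambda)
      stop(sprintf("`slambda` (%g) exceeds 180%% of `lambda` (cap %g)",
                   p$slambda, 1.8 * p$lambda), call. = FALSE)
  }
  if (p$variant == "GCDF_KB") {
    if (is.null(p$xi) || !is.finite(p$xi) || p$xi < 0)
      stop("variant GCDF_KB requires `xi` >= 0", call. = FALSE)
  }
  if (p$sx0 > 1.8 * p$g)
    stop(sprintf("`sx0` (%g) exceeds 180%% of `g` (cap %g)",
                 p$sx0, 1.8 * p$g), call. = FALSE)
  # Te may be per-condition: the cap must hold against each mean
  if (p$sTe > 1.8 * min(p$Te))
    stop(sprintf("`sTe` (%g) exceeds 180%% of `Te` (cap %g)",
                 p$sTe, 1.8 * min(p$Te)), call. = FALSE)
  if (p$sTr > 1.8 * min(p$Tr))
    stop(sprintf("`sTr` (%g) exceeds 180%% of `Tr` (cap %g)",
                 p$sTr, 1.8 * min(p$Tr)), call. = FALSE)
  params
}

#' @export
print.gcdf_params <- function(x, ...) {
  cat("<gcdf_params> variant:", x$variant, "\n")
  main <- c(sigma = x$sigma, g = x$g, r = x$r,
            Te = if (length(x$Te) == 1) x$Te else NA, Tr = x$Tr, x0 = x$x0)
  if (!is.null(x$lambda)) main <- c(main, lambda = x$lambda)
  if (!is.null(x$xi)) main <- c(main, xi = x$xi)
  print(round(main, 4))
  if (length(x$Te) > 1) { cat("  Te (per condition):\n"); print(round(x$Te, 4)) }
  vv <- c(sv = x$sv, sx0 = x$sx0, sTe = x$sTe, sTr = x$sTr, slambda = x$slambda)
  if (any(vv > 0)) { cat("  between-trial variability:\n"); print(round(vv, 4)) }
  invisible(x)
}
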