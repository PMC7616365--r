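#' Drift maps: from experimental condition to mean drift rate
#'
#' A drift map encodes the experiment-specific rule relating a condition to
#' the mean drift rate of the decision stage, together with optional
#' per-condition overrides of the residual latency `Te` and the
#' between-trial drift variability `sv`.
#'
#' Three forms are supported:
#' \describe{
#'   \item{linear (motion coherence)}{`v = k * coherence`; conditions are
#'     numeric coherence levels.}
#'   \item{criterion (numerosity)}{`v = v1 * (count - criterion) + dc`,
#'     with a signed additive drift criterion `dc` and criterion quantity
#'     50 by default; conditions are numeric dot counts.}
#'   \item{per-condition}{a free drift per named condition (memory strength,
#'     word frequency, ...).}
#' }
#'
#' @param k slope of the linear coherence-to-drift rule (evidence-units/s
#'   per unit coherence).
#' @param v1 scaling of the numerosity difference (evidence-units/s per dot).
#' @param dc additive drift criterion (signed, evidence-units/s).
#' @param criterion criterion quantity (default 50 dots).
#' @param v named numeric vector of per-condition mean drifts.
#' @param Te optional named numeric vector of per-condition mean residual
#'   latencies (s), overriding the scalar `Te` in [gcdf_params()].
#' @param sv optional per-condition drift variability: a named numeric
#'   vector, or a function of the (numeric) condition value returning an
#'   SD, overriding the scalar `sv` in [gcdf_params()].
#' @return an object of class `gcdf_drift_map`.
#' @seealso [drift_for_condition()], [sv_rule_numerosity()]
#' @name drift_maps
NULL

new_drift_map <- function(form, fields, Te = NULL, sv = NULL) {
  structure(c(list(form = form), fields, list(Te = Te, sv = sv)),
            class = "gcdf_drift_map")
}

#' @rdname drift_maps
#' @export
drift_linear <- function(k, Te = NULL, sv = NULL) {
  stopifnot(is.numeric(k), length(k) == 1)
  new_drift_map("linear_coherence", list(k = k), Te, sv)
}

#' @rdname drift_maps
#' @export
drift_criterion <- function(v1, dc = 0, criterion = 50, Te = NULL, sv = NULL) {
  stopifnot(is.numeric(v1), length(v1) == 1, is.numeric(dc))
  new_drift_map("numerosity_criterion",
                list(v1 = v1, dc = dc, criterion = criterion), Te, sv)
}

#' @rdname drift_maps
#' @export
drift_conditions <- function(v, Te = NULL, sv = NULL) {
  stopifnot(is.numeric(v), !is.null(names(v)), all(nzchar(names(v))))
  new_drift_map("per_condition", list(v = v), Te, sv)
}

#' Mean drift rate for a condition
#'
#' Resolves a condition to its mean drift under a drift map: the linear
#' form returns `k * coherence`, the criterion form
#' `v1 * (count - criterion) + dc`, and the per-condition form the stored
#' drift for that condition label.
#'
#' @param map a `gcdf_drift_map`.
#' @param condition numeric condition value (linear and criterion forms) or
#'   condition label (per-condition form). Vectorized.
#' @return mean drift rate(s), evidence-units/s.
#' @export
drift_for_condition <- function(map, condition) {
  stopifnot(inherits(map, "gcdf_drift_map"))
  switch(map$form,
    linear_coherence = {
      val <- as.numeric(condition)
      if (any(is.na(val))) stop("linear drift map needs numeric coherence")
      map$k * val
    },
    numerosity_criterion = {
      val <- as.numeric(condition)
      if (any(is.na(val))) stop("criterion drift map needs numeric counts")
      map$v1 * (val - map$criterion) + map$dc
    },
    per_condition = {
      key <- as.character(condition)
      unknown <- setdiff(key, names(map$v))
      if (length(unknown))
        stop("unknown condition(s): ", paste(unknown, collapse = ", "))
      unname(map$v[key])
    })
}

#' Drift-variability rule for numerosity designs
#'
#' Default pluggable rule for the increase of drift variability with dot
#' count in criterion-type numerosity designs, reflecting approximate
#' number representations whose spread grows with magnitude:
#' `sv(count) = sqrt(eta0^2 + (sigma1 * count)^2)`.
#'
#' @param sigma1 linear scaling of representational spread with count.
#' @param eta0 count-independent variability floor.
#' @return a function of the dot count, usable as the `sv` field of a
#'   drift map.
#' @export
sv_rule_numerosity <- function(sigma1, eta0) {
  force(sigma1); force(eta0)
  function(count) sqrt(eta0^2 + (sigma1 * as.numeric(count))^2)
}

# Resolve the per-condition moments (mean drift, sv, Te) actually used by
# the sampler, honouring map-level overrides. `value` is the numeric
# condition value (coherence, count) where applicable, `label` the name.
condition_moments <- function(params, map, label, value = label) {
  cond <- if (map$form == "per_condition") label else value
  v <- drift_for_condition(map, cond)
  sv <- params$sv
  if (!is.null(map$sv)) {
    sv <- if (is.function(map$sv)) map$sv(value) else {
      if (!as.character(label) %in% names(map$sv))
        stop("no sv override for condition ", label)
      unname(map$sv[as.character(label)])
    }
  }
  Te <- params$Te
  if (!is.null(map$Te)) {
    if (!as.character(label) %in% names(map$Te))
      stop("no Te override for condition ", label)
    Te <- unname(map$Te[as.character(label)])
  }
  list(v = v, sv = sv, Te = Te)
}

#' @export
print.gcdf_drift_map <- function(x, ...) {
  cat("<gcdf_drift_map> form:", x$form, "\n")
  fields <- switch(x$form,
    linear_coherence = c(k = x$k),
    numerosity_criterion = c(v1 = x$v1, dc = x$dc, criterion = x$criterion),
    per_condition = x$v)
  print(fields)
  if (!is.null(x$Te)) { cat("  per-condition Te:\n"); print(x$Te) }
  if (!is.null(x$sv)) cat("  per-condition sv:",
                          if (is.function(x$sv)) "<rule function>" else
                            paste(format(x$sv), collapse = " "), "\n")
  invisible(x)
}
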