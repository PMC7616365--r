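#' Experiment design templates
#'
#' Builds the condition structure of the four study templates:
#' \describe{
#'   \item{exp1 (motion perception)}{six motion-coherence levels
#'     (0, .05, .08, .12, .2, .4), 192 trials each, 5 s deadline, linear
#'     coherence-to-drift map. Positive evidence favours the correct
#'     response, so the correct channel is `"upper"` throughout.}
#'   \item{exp2 (numerosity)}{eight dot-count bins represented by their
#'     means (33, 38, 43, 48, 53, 58, 63, 68), 4 s deadline, criterion
#'     drift map against 50; counts above the criterion make `"upper"`
#'     ("greater") correct.}
#'   \item{exp3 (recognition memory)}{words studied one, two or four
#'     times plus new words, 4 s deadline, per-condition drifts;
#'     `"upper"` ("old") is correct for studied words.}
#'   \item{exp4 (lexical decision)}{very-low to high frequency words plus
#'     pseudowords, 4 s deadline, per-condition drifts and residual
#'     latencies; `"upper"` ("word") is correct for words.}
#' }
#' Trial counts per condition for exp2-exp4 are not part of the template
#' source and default to 192 to parallel exp1; override with `n_trials`.
#'
#' @param template one of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`.
#' @param n_trials optional per-condition trial count override (scalar or
#'   vector over conditions).
#' @return an object of class `gcdf_design`: data frame with columns
#'   `condition`, `value`, `n_trials`, `correct_channel` and attributes
#'   `deadline`, `drift_form`, `name`.
#' @export
make_design <- function(template = c("exp1", "exp2", "exp3", "exp4"),
                        n_trials = NULL) {
  template <- match.arg(template)
  d <- switch(template,
    exp1 = data.frame(
      condition = c("0", "0.05", "0.08", "0.12", "0.2", "0.4"),
      value = c(0, .05, .08, .12, .2, .4),
      n_trials = 192L,
      correct_channel = "upper", stringsAsFactors = FALSE),
    exp2 = data.frame(
      condition = as.character(seq(33, 68, by = 5)),
      value = seq(33, 68, by = 5),
      n_trials = 192L,
      correct_channel = ifelse(seq(33, 68, by = 5) > 50, "upper", "lower"),
      stringsAsFactors = FALSE),
    exp3 = data.frame(
      condition = c("old1", "old2", "old4", "new"),
      value = NA_real_,
      n_trials = 192L,
      correct_channel = c("upper", "upper", "upper", "lower"),
      stringsAsFactors = FALSE),
    exp4 = data.frame(
      condition = c("VLF", "LF", "MF", "HF", "pseudo"),
      value = NA_real_,
      n_trials = 192L,
      correct_channel = c("upper", "upper", "upper", "upper", "lower"),
      stringsAsFactors = FALSE))
  if (!is.null(n_trials)) d$n_trials <- as.integer(n_trials)
  if (any(d$n_trials <= 0)) stop("trial counts must be > 0")
  structure(d,
            deadline = if (template == "exp1") 5 else 4,
            drift_form = switch(template, exp1 = "linear_coherence",
                                exp2 = "numerosity_criterion",
                                "per_condition"),
            name = template,
            class = c("gcdf_design", "data.frame"))
}

#' Published full-model parameter presets
#'
#' Group-average best-fitting parameters of the full (between-trial
#' variability) model variants for the four experiment templates, as a
#' ready-made `(params, map)` pair. `form = "raw"` zeroes the variability
#' terms, giving a synthetic raw-model parameter set built from the full
#' fits (the raw averages themselves are not part of the source tables).
#'
#' @param experiment `"exp1"` to `"exp4"`.
#' @param variant `"GCDF"` or `"GCD"`.
#' @param form `"full"` (variability as fitted) or `"raw"` (variability
#'   zeroed).
#' @return list with elements `params` ([gcdf_params()]) and `map`
#'   ([drift_maps]).
#' @export
preset_params <- function(experiment = c("exp1", "exp2", "exp3", "exp4"),
                          variant = c("GCDF", "GCD"),
                          form = c("full", "raw")) {
  experiment <- match.arg(experiment)
  variant <- match.arg(variant)
  form <- match.arg(form)
  full <- form == "full"
  z <- function(x) if (full) x else 0

  if (experiment == "exp1") {
    if (variant == "GCDF") {
      params <- gcdf_params("GCDF", g = 0.069, r = 0.022, Te = 0.283,
                            Tr = 0.093, x0 = 0, lambda = 21.471,
                            sv = z(0.117), sx0 = z(0.074), sTe = z(0.203),
                            sTr = z(0.076), slambda = z(29.423))
      map <- drift_linear(k = 1.183)
    } else {
      params <- gcdf_params("GCD", g = 0.091, r = 0.005, Te = 0.353,
                            Tr = 0.169, x0 = 0,
                            sv = z(0.134), sx0 = z(0.085), sTe = z(0.286),
                            sTr = z(0.168))
      map <- drift_linear(k = 1.534)
    }
  } else if (experiment == "exp2") {
    if (variant == "GCDF") {
      params <- gcdf_params("GCDF", g = 0.042, r = 0.030, Te = 0.339,
                            Tr = 0.106, x0 = 0.000, lambda = 57.842,
                            sx0 = z(0.060), sTe = z(0.225), sTr = z(0.078),
                            slambda = z(82.803))
      map <- drift_criterion(v1 = 0.023, dc = -0.011,
                             sv = if (full)
                               sv_rule_numerosity(0.001, 0.042) else NULL)
    } else {
      params <- gcdf_params("GCD", g = 0.065, r = 0.036, Te = 0.474,
                            Tr = 0.148, x0 = 0.006,
                            sx0 = z(0.098), sTe = z(0.422), sTr = z(0.133))
      map <- drift_criterion(v1 = 0.066, dc = -0.035,
                             sv = if (full)
                               sv_rule_numerosity(0.007, 0.050) else NULL)
    }
  } else if (experiment == "exp3") {
    conds <- c("old1", "old2", "old4", "new")
    if (variant == "GCDF") {
      params <- gcdf_params("GCDF", g = 0.037, r = 0.031, Te = 0.452,
                            Tr = 0.099, x0 = 0.000, lambda = 73.158,
                            sx0 = z(0.052), sTe = z(0.204), sTr = z(0.065),
                            slambda = z(86.538))
      map <- drift_conditions(
        stats::setNames(c(0.138, 0.288, 0.399, -0.342), conds),
        sv = if (full)
          stats::setNames(c(0.335, 0.313, 0.263, 0.163), conds) else NULL)
    } else {
      params <- gcdf_params("GCD", g = 0.045, r = 0.024, Te = 0.544,
                            Tr = 0.139, x0 = 0.001,
                            sx0 = z(0.065), sTe = z(0.327), sTr = z(0.113))
      map <- drift_conditions(
        stats::setNames(c(0.207, 0.518, 0.739, -0.656), conds),
        sv = if (full)
          stats::setNames(c(0.439, 0.427, 0.426, 0.274), conds) else NULL)
    }
  } else {
    conds <- c("VLF", "LF", "MF", "HF", "pseudo")
    if (variant == "GCDF") {
      params <- gcdf_params("GCDF", g = 0.041, r = 0.035, Te = 0.454,
                            Tr = 0.109, x0 = -0.006, lambda = 122.938,
                            sx0 = z(0.057), sTe = z(0.350), sTr = z(0.075),
                            slambda = z(146.702))
      map <- drift_conditions(
        stats::setNames(c(0.277, 0.393, 0.460, 0.517, -0.301), conds),
        Te = stats::setNames(c(0.500, 0.471, 0.454, 0.430, 0.489), conds),
        sv = if (full)
          stats::setNames(c(0.334, 0.266, 0.208, 0.195, 0.122), conds)
          else NULL)
    } else {
      params <- gcdf_params("GCD", g = 0.046, r = 0.036, Te = 0.549,
                            Tr = 0.133, x0 = -0.004,
                            sx0 = z(0.071), sTe = z(0.456), sTr = z(0.107))
      map <- drift_conditions(
        stats::setNames(c(0.459, 0.683, 0.809, 0.878, -0.571), conds),
        Te = stats::setNames(c(0.589, 0.571, 0.549, 0.512, 0.581), conds),
        sv = if (full)
          stats::setNames(c(0.522, 0.435, 0.372, 0.312, 0.267), conds)
          else NULL)
    }
  }
  list(params = params, map = map)
}
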