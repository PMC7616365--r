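#' Generate a synthetic "observed" dataset with a truth record
#'
#' Simulates an experiment-shaped trial table from known true parameters
#' and packages it with a truth record (parameters, drift map, design,
#' seed, package version) so that parameter-recovery studies can score
#' estimates against the generating values and the table can be
#' regenerated bit-identically.
#'
#' @param params,map the true generating model ([gcdf_params()],
#'   [drift_maps]).
#' @param design a [make_design()] design.
#' @param seed master seed.
#' @param config a [sim_config()].
#' @param path optional directory; when given, the trial table is written
#'   to `<path>/trials.tsv` and the truth record to `<path>/truth.json`.
#' @param subject_id subject label stored in the serialized table.
#' @return list with elements `table` (trial table) and `truth` (list).
#' @export
generate_observed_dataset <- function(params, map, design, seed,
                                      config = sim_config(), path = NULL,
                                      subject_id = "synthetic01") {
  validate_params(params)
  table <- simulate_dataset(params, map, design, config, seed = seed)
  truth <- list(
    params = unclass(params),
    map = lapply(unclass(map), function(f)
      if (is.function(f)) deparse(f) else f),
    design = list(name = attr(design, "name"),
                  condition = design$condition, value = design$value,
                  n_trials = design$n_trials,
                  correct_channel = design$correct_channel,
                  deadline = attr(design, "deadline")),
    seed = seed,
    sim = list(dt = config$dt,
               max_decision_time = config$max_decision_time,
               min_burst_duration = config$min_burst_duration),
    package_version = as.character(utils::packageVersion("gcdf")))
  if (!is.null(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(table, file.path(path, "trials.tsv"),
                      subject_id = subject_id)
    jsonlite::write_json(truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  list(table = table, truth = truth)
}

#' Jittered synthetic subject cohort
#'
#' Builds a cohort of per-subject parameter sets by jittering a truth
#' parameter set with small multiplicative dispersions (lognormal with
#' the given coefficient of variation), emulating between-subject
#' variation for model-selection tally tests. Dispersions are synthetic:
#' real between-subject spread is unknown.
#'
#' @param params,map truth model.
#' @param n_subjects cohort size.
#' @param cv coefficient of variation of the multiplicative jitter.
#' @param seed RNG seed.
#' @return list of per-subject `list(params, map)` pairs.
#' @export
synthetic_cohort <- function(params, map, n_subjects = 18, cv = 0.1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  jitter1 <- function(x) x * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  lapply(seq_len(n_subjects), function(i) {
    p <- params
    for (f in c("g", "r", "Te", "Tr", "lambda"))
      if (!is.null(p[[f]])) p[[f]] <- jitter1(p[[f]])
    m <- map
    if (m$form == "linear_coherence") m$k <- jitter1(m$k)
    if (m$form == "numerosity_criterion") m$v1 <- jitter1(m$v1)
    if (m$form == "per_condition") m$v <- vapply(m$v, jitter1, numeric(1))
    list(params = validate_params(p), map = m)
  })
}

#' Degenerate fixtures for exact-value tests
#'
#' Small, fully deterministic inputs with known closed-form outputs:
#' \describe{
#'   \item{ramp}{a noise-free unfiltered trial (drift 0.2, gate 0.05,
#'     threshold 0.02, residual latencies 0.3/0.1 s) whose PMT, MT and RT
#'     are 0.550, 0.200 and 0.750 s by construction.}
#'   \item{burst_trajectory}{a handcrafted motor-preparation path that
#'     rises above the gate, falls back, recrosses and hits threshold:
#'     exactly one partial burst in the upper channel.}
#'   \item{type_table}{a 10-trial table with six-type counts
#'     (6, 1, 1, 1, 1, 0).}
#'   \item{tie_table}{a table with one trial exactly on a PMT bin
#'     boundary (goes to the lower bin under the tie rule).}
#' }
#'
#' @return named list of fixtures; each element records what it is for.
#' @export
degenerate_fixtures <- function() {
  ramp_params <- gcdf_params("GCD", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1,
                             sigma = 0, sigma_free = TRUE)
  ramp <- list(params = ramp_params, map = drift_linear(k = 1),
               condition = 0.2,
               expected = c(pmt = 0.550, mt = 0.200, rt = 0.750))

  # y rises to just above the gate, dips below, recrosses and climbs to r
  dt <- 0.001
  g <- 0.05; r <- 0.02
  y <- c(seq(0, 0.055, by = 0.005),        # crosses g = 0.05 (burst)
         seq(0.050, 0.040, by = -0.005),   # back below the gate
         seq(0.045, 0.075, by = 0.005))    # recrosses and hits g + r
  burst_traj <- list(t = (seq_along(y) - 1) * dt, y = y, dt = dt,
                     g = g, r = r, expected_bursts = 1L,
                     expected_channel = "upper")

  type_counts <- c(pureC = 6L, CC = 1L, IC = 1L, pureI = 1L, II = 1L, CI = 0L)
  mk_row <- function(type, i) {
    acc <- type %in% c("pureC", "CC", "IC")
    first <- switch(type, CC = "upper", IC = "lower",
                    II = "lower", CI = "upper", NA_character_)
    data.frame(condition = "c1", value = NA_real_, trial = i, seed = i,
               correct_channel = "upper",
               response = if (acc) "upper" else "lower", accuracy = acc,
               tg = 0.25, decision_time = 0.35,
               pmt = 0.5 + 0.01 * i, mt = 0.2 + 0.005 * i,
               rt = 0.7 + 0.015 * i,
               n_bursts = if (is.na(first)) 0L else 1L,
               first_burst_channel = first,
               first_burst_latency = if (is.na(first)) NA_real_ else 0.4,
               omitted = FALSE, stringsAsFactors = FALSE)
  }
  types <- rep(names(type_counts), type_counts)
  type_table <- do.call(rbind, Map(mk_row, types, seq_along(types)))
  rownames(type_table) <- NULL

  tie_table <- type_table
  tie_table$pmt <- seq(0.40, 0.85, by = 0.05)
  tie_table$mt <- seq(0.10, 0.55, by = 0.05)
  tie_table$rt <- tie_table$pmt + tie_table$mt

  list(ramp = ramp, burst_trajectory = burst_traj,
       type_table = list(table = type_table, counts = type_counts),
       tie_table = tie_table)
}
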