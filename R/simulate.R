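#' Simulation configuration
#'
#' @param dt integration time step (s); 0.001 matches the 1 ms granularity
#'   of behavioural and EMG recordings.
#' @param max_decision_time decision-stage deadline (s); trials whose
#'   neural drive has not reached threshold by then are omissions.
#' @param min_burst_duration minimum duration (s) for a positive excursion
#'   of the neural drive to count as a partial burst; the default of one
#'   time step counts every excursion. Larger values emulate artifact
#'   rejection.
#' @param record_trajectories keep the full `x`/`y` paths of each trial
#'   (memory-heavy; single-trial use).
#' @return an object of class `gcdf_sim_config`.
#' @export
sim_config <- function(dt = 0.001, max_decision_time = 5,
                       min_burst_duration = dt,
                       record_trajectories = FALSE) {
  stopifnot(dt > 0, max_decision_time > 0, min_burst_duration > 0)
  n_steps <- max_decision_time / dt
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("`max_decision_time` must be an integer multiple of `dt`")
  structure(list(dt = dt, max_decision_time = max_decision_time,
                 max_steps = as.integer(round(n_steps)),
                 min_burst_duration = min_burst_duration,
                 min_burst_steps = max(1L, as.integer(round(min_burst_duration / dt))),
                 record_trajectories = isTRUE(record_trajectories)),
            class = "gcdf_sim_config")
}

#' Integrate one trial of the cascaded stochastic system
#'
#' Euler-Maruyama integration of the decision diffusion and, for the
#' filtered variants, of the motor-preparation filter, on the grid
#' `t_n = n dt`, recording the full paths. The per-step filter gain
#' `lambda * dt` (or the Kalman-Bucy gain `lambda tanh(lambda t) dt`) is
#' capped at 1, so arbitrarily fast filters degrade gracefully into `y`
#' tracking `x` with a one-step delay rather than becoming unstable.
#'
#' @param realized a `gcdf_trial_params` object ([sample_trial_params()]).
#' @param params the `gcdf_params` the trial was drawn from (supplies
#'   `sigma`, `g`, `r`, `xi`, variant).
#' @param config a [sim_config()].
#' @param stop_at_threshold stop at the first grid point where the neural
#'   drive reaches `r` (default); `FALSE` integrates the full horizon
#'   (filter-oracle checks).
#' @return an object of class `gcdf_trajectory`: list with the time grid
#'   `t`, paths `x`, `y`, `zL`, `zR`, and the raw event fields from the
#'   integrator.
#' @export
integrate_paths <- function(realized, params, config = sim_config(),
                            stop_at_threshold = TRUE) {
  stopifnot(inherits(realized, "gcdf_trial_params"),
            inherits(params, "gcdf_params"),
            inherits(config, "gcdf_sim_config"))
  kb <- params$variant == "GCDF_KB"
  res <- cpp_integrate(realized$v, realized$x0, realized$lambda,
                       if (kb) params$xi else 0,
                       params$sigma, params$g, params$r, config$dt,
                       config$max_steps, config$min_burst_steps, kb,
                       stop_at_threshold)
  y <- res$y
  out <- list(t = (seq_along(y) - 1) * config$dt,
              x = res$x, y = y,
              zL = pmax(-y - params$g, 0), zR = pmax(y - params$g, 0),
              hit_idx = res$hit_idx, tg_idx = res$tg_idx,
              channel = res$channel,
              dt = config$dt)
  class(out) <- "gcdf_trajectory"
  out
}

#' Extract trial events from a trajectory
#'
#' Segments the positive excursions of the neural drive and derives the
#' trial events: the threshold hit (first grid point with `zL` or
#' `zR >= r`), the EMG-onset time `t_g` (last grid point with zero drive
#' before the final excursion), and the partial bursts (all earlier
#' maximal positive excursions, in either channel, of duration at least
#' `min_burst_duration`), ordered by onset. Burst onsets use the same
#' last-zero-point convention as `t_g`. A trial with no threshold crossing
#' before the deadline is an omission, returned as a value rather than an
#' error.
#'
#' @param traj a `gcdf_trajectory` (or any list with `t` and `y`).
#' @param g gating inhibition.
#' @param r response threshold.
#' @param config a [sim_config()] (supplies `min_burst_duration`).
#' @return list with `omitted` flag and, for non-omitted trials, `tg`,
#'   `hit_time`, `channel` (`"upper"` or `"lower"`), and a data frame
#'   `bursts` with columns `channel`, `onset`, `duration`.
#' @export
extract_events <- function(traj, g, r, config = sim_config()) {
  y <- traj$y
  tt <- traj$t
  dt <- if (!is.null(traj$dt)) traj$dt else tt[2] - tt[1]
  zR <- y - g
  zL <- -y - g
  ch <- integer(length(y))
  ch[zR > 0] <- 1L
  ch[zL > 0] <- -1L
  hit <- which((ch == 1L & zR >= r) | (ch == -1L & zL >= r))
  if (!length(hit))
    return(list(omitted = TRUE, tg = NA_real_, hit_time = NA_real_,
                channel = NA_character_,
                bursts = data.frame(channel = character(), onset = numeric(),
                                    duration = numeric())))
  hit <- hit[1]
  # maximal runs of constant channel up to the hit
  runs <- rle(ch[seq_len(hit)])
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pos <- which(runs$values != 0L)
  fin <- pos[length(pos)]                      # run containing the hit
  onset_time <- function(i) tt[max(starts[i] - 1L, 1L)]
  min_steps <- config$min_burst_steps
  before <- pos[pos != fin & runs$lengths[pos] >= min_steps]
  bursts <- data.frame(
    channel = ifelse(runs$values[before] == 1L, "upper", "lower"),
    onset = vapply(before, onset_time, numeric(1)),
    duration = runs$lengths[before] * dt)
  list(omitted = FALSE,
       tg = onset_time(fin),
       hit_time = tt[hit],
       channel = if (runs$values[fin] == 1L) "upper" else "lower",
       bursts = bursts[order(bursts$onset), , drop = FALSE])
}

#' Simulate a single trial
#'
#' Composes [sample_trial_params()], [integrate_paths()] and
#' [extract_events()] into one trial record. The premotor time is
#' `Te_trial + t_g`; the motor time is `(hit - t_g) + Tr_trial`; partial
#' burst latencies are referenced to stimulus onset (`Te_trial + onset`).
#' Given a seed set immediately before the call, the record is exactly
#' reproducible, and matches the corresponding row of
#' [simulate_dataset()] run with the same trial seed.
#'
#' @inheritParams sample_trial_params
#' @param config a [sim_config()].
#' @param correct_channel which channel (`"upper"`/`"lower"`) counts as
#'   correct for this condition, or `NA` to skip accuracy coding.
#' @return an object of class `gcdf_trial`: list with `condition`,
#'   `response`, `accuracy`, `tg`, `decision_time`, `pmt`, `mt`, `rt`,
#'   `bursts` (stimulus-locked onsets), `omitted`, `realized`, and the
#'   trajectory when `config$record_trajectories` is set.
#' @export
simulate_trial <- function(params, map, condition, config = sim_config(),
                           value = condition, correct_channel = NA) {
  realized <- sample_trial_params(params, map, condition, value)
  traj <- integrate_paths(realized, params, config)
  ev <- extract_events(traj, params$g, params$r, config)
  rec <- list(condition = condition, omitted = ev$omitted,
              realized = realized)
  if (ev$omitted) {
    rec[c("response", "accuracy", "tg", "decision_time", "pmt", "mt", "rt")] <-
      list(NA_character_, NA, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
    rec$bursts <- ev$bursts
  } else {
    bursts <- ev$bursts
    bursts$onset <- realized$Te + bursts$onset
    rec$response <- ev$channel
    rec$accuracy <- if (is.na(correct_channel)) NA else
      identical(ev$channel, correct_channel)
    rec$tg <- ev$tg
    rec$decision_time <- ev$hit_time
    rec$pmt <- realized$Te + ev$tg
    rec$mt <- (ev$hit_time - ev$tg) + realized$Tr
    rec$rt <- rec$pmt + rec$mt
    rec$bursts <- bursts
  }
  if (config$record_trajectories) rec$trajectory <- traj
  class(rec) <- "gcdf_trial"
  rec
}

#' Simulate a full experiment-shaped trial table
#'
#' Simulates every condition of a design with per-condition trial counts,
#' deriving one RNG seed per trial from the master seed so that any trial
#' can be regenerated in isolation and matched-seed comparisons across
#' parameter settings reuse identical noise streams per trial index.
#'
#' @param params a validated [gcdf_params()].
#' @param map a [drift_maps] object.
#' @param design a [make_design()] object, or any data frame with columns
#'   `condition`, `value`, `n_trials`, `correct_channel`.
#' @param config a [sim_config()]; when the design carries a `deadline`
#'   attribute it overrides `max_decision_time`.
#' @param seed master seed (integer). Set it for reproducible tables; the
#'   per-trial seeds are drawn from it up front.
#' @return a `data.frame` with one row per trial: `condition`, `value`,
#'   `trial`, `seed`, `correct_channel`, `response`, `accuracy`, `tg`,
#'   `decision_time`, `pmt`, `mt`, `rt`, `n_bursts`,
#'   `first_burst_channel`, `first_burst_latency`, `omitted`. The
#'   per-condition omission rates are attached as attribute
#'   `omission_rate`.
#' @export
simulate_dataset <- function(params, map, design, config = sim_config(),
                             seed = NULL) {
  stopifnot(inherits(params, "gcdf_params"))
  if (!nrow(design)) stop("empty design")
  if (!is.null(attr(design, "deadline", exact = TRUE)) &&
      attr(design, "deadline") != config$max_decision_time)
    config <- sim_config(config$dt, attr(design, "deadline"),
                         config$min_burst_duration,
                         config$record_trajectories)
  if (!is.null(seed)) set.seed(seed)
  n_total <- sum(design$n_trials)
  seeds <- sample.int(.Machine$integer.max, n_total)
  kb <- params$variant == "GCDF_KB"
  lambda <- if (params$variant == "GCD") Inf else params$lambda
  out <- vector("list", nrow(design))
  off <- 0L
  for (i in seq_len(nrow(design))) {
    n <- design$n_trials[i]
    m <- condition_moments(params, map, design$condition[i], design$value[i])
    trial_seeds <- seeds[off + seq_len(n)]
    off <- off + n
    sim <- cpp_sim_dataset(trial_seeds, m$v, m$sv,
                           params$x0, params$sx0, m$Te, params$sTe,
                           params$Tr, params$sTr, lambda, params$slambda,
                           if (kb) params$xi else 0,
                           params$sigma, params$g, params$r,
                           config$dt, config$max_steps,
                           config$min_burst_steps, kb)
    resp <- ifelse(is.na(sim$response), NA_character_,
                   ifelse(sim$response == 1L, "upper", "lower"))
    fb <- ifelse(is.na(sim$first_burst_channel), NA_character_,
                 ifelse(sim$first_burst_channel == 1L, "upper", "lower"))
    out[[i]] <- data.frame(
      condition = design$condition[i], value = design$value[i],
      trial = seq_len(n), seed = trial_seeds,
      correct_channel = design$correct_channel[i],
      response = resp,
      accuracy = ifelse(is.na(resp), NA,
                        resp == design$correct_channel[i]),
      tg = sim$tg, decision_time = sim$hit,
      pmt = sim$pmt, mt = sim$mt, rt = sim$pmt + sim$mt,
      n_bursts = sim$n_bursts,
      first_burst_channel = fb,
      first_burst_latency = sim$first_burst_latency,
      omitted = sim$omitted,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  om <- tapply(tab$omitted, tab$condition, mean)
  attr(tab, "omission_rate") <- om[unique(tab$condition)]
  tab
}
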