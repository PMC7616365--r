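#' Classify a trial into the six-type taxonomy
#'
#' A trial is classified by its response accuracy and the channel of its
#' first partial burst: `pureC` / `pureI` when no partial burst occurred
#' during the premotor time, otherwise the first burst's channel (coded
#' correct/incorrect) prefixed to the response, giving `CC`, `IC`, `II`,
#' `CI`. The same taxonomy applies to category-coded designs (the correct
#' channel per condition plays the role of the positive-evidence
#' response).
#'
#' @param record a `gcdf_trial` from [simulate_trial()] (non-omitted).
#' @return one of `"pureC"`, `"CC"`, `"IC"`, `"pureI"`, `"II"`, `"CI"`.
#' @export
classify_trial <- function(record) {
  if (isTRUE(record$omitted)) stop("cannot classify an omitted trial")
  if (is.na(record$accuracy))
    stop("trial has no accuracy coding; supply `correct_channel`")
  resp <- if (record$accuracy) "C" else "I"
  if (!nrow(record$bursts)) return(paste0("pure", resp))
  correct_ch <- if (record$accuracy) record$response else
    setdiff(c("upper", "lower"), record$response)
  first <- record$bursts$channel[1]
  paste0(if (first == correct_ch) "C" else "I", resp)
}

trial_type_levels <- c("pureC", "CC", "IC", "pureI", "II", "CI")

# vectorized classification over a trial table (non-omitted rows)
classify_table <- function(table) {
  resp <- ifelse(table$accuracy, "C", "I")
  type <- paste0("pure", resp)
  has <- !is.na(table$n_bursts) & table$n_bursts > 0
  first_correct <- table$first_burst_channel == table$correct_channel
  type[has] <- paste0(ifelse(first_correct[has], "C", "I"), resp[has])
  factor(type, levels = trial_type_levels)
}

#' Per-condition proportions of the six trial types
#'
#' @param table a trial table from [simulate_dataset()] or
#'   [read_trial_table()]. Omitted trials are excluded.
#' @return a data frame with one row per condition and one column per
#'   trial type (`pureC`, `CC`, `IC`, `pureI`, `II`, `CI`); proportions
#'   sum to 1 per condition.
#' @export
trial_type_proportions <- function(table) {
  tab <- table[!table$omitted, , drop = FALSE]
  if (!nrow(tab)) stop("no non-omitted trials")
  type <- classify_table(tab)
  counts <- table(condition = tab$condition, type = type)
  if (any(rowSums(counts) == 0)) stop("condition with no non-omitted trials")
  props <- prop.table(counts, margin = 1)
  out <- data.frame(condition = rownames(props), unclass(as.matrix(props)),
                    stringsAsFactors = FALSE, row.names = NULL)
  # keep the design's condition order
  out[match(unique(as.character(tab$condition)), out$condition), ,
      drop = FALSE]
}

#' Order-statistic quantiles with linear interpolation
#'
#' Quantiles by linear interpolation between the closest order statistics
#' (the rule where sorted value `x_(k)` sits at probability
#' `(k - 1) / (n - 1)`); the convention is fixed and documented so that
#' observed and simulated summaries are always computed identically.
#'
#' @param values nonempty numeric vector.
#' @param probs probabilities in (0, 1); default the five quantiles
#'   (.1, .3, .5, .7, .9) used for the binned fit statistic.
#' @return quantile vector, nondecreasing in `probs`.
#' @export
empirical_quantiles <- function(values, probs = c(.1, .3, .5, .7, .9)) {
  if (!length(values)) stop("empty input")
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
  stats::quantile(values, probs = probs, type = 7, names = FALSE)
}

#' Quantile summary / quantile probability functions
#'
#' Per condition and response class (correct vs incorrect), the PMT and MT
#' quantiles together with the response-class proportion: the building
#' blocks of quantile probability plots. Incorrect-response quantiles are
#' reported only when the class has at least `min_count` trials in every
#' condition, mirroring the usual display rule for error distributions.
#'
#' @param table a trial table; omitted trials are excluded.
#' @param probs quantile probabilities; the default five summarize the
#'   distribution shape, `seq(.1, .9, .1)` gives the nine deciles used for
#'   PMT-MT quantile plots.
#' @param min_count minimum per-condition trial count for the incorrect
#'   class to be reported (default 10).
#' @return a data frame with columns `condition`, `class`, `proportion`,
#'   `n`, `prob`, `pmt`, `mt` (long format over `probs`).
#' @export
quantile_summary <- function(table, probs = c(.1, .3, .5, .7, .9),
                             min_count = 10) {
  tab <- table[!table$omitted, , drop = FALSE]
  conds <- unique(as.character(tab$condition))
  min_err <- min(vapply(conds, function(cc)
    sum(!tab$accuracy[tab$condition == cc]), numeric(1)))
  out <- list()
  for (cc in conds) {
    sub <- tab[tab$condition == cc, , drop = FALSE]
    for (cls in c("correct", "incorrect")) {
      sel <- if (cls == "correct") sub$accuracy else !sub$accuracy
      n <- sum(sel)
      if (cls == "incorrect" && min_err < min_count) next
      if (n == 0) next
      out[[length(out) + 1L]] <- data.frame(
        condition = cc, class = cls,
        proportion = n / nrow(sub), n = n, prob = probs,
        pmt = empirical_quantiles(sub$pmt[sel], probs),
        mt = empirical_quantiles(sub$mt[sel], probs),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Partial-burst statistics per condition
#'
#' Proportion of trials with at least one partial burst during the
#' premotor time, and the mean stimulus-locked latency of the first burst
#' (over trials that have one). Two latency aggregates are available for
#' multi-subject tables: trial-weighted (pooling all trials) and
#' subject-mean (averaging within subject first).
#'
#' @param table a trial table; omitted trials are excluded.
#' @param correct_only restrict to correct trials (default, matching the
#'   usual reporting convention).
#' @param by_subject if `TRUE` and the table has a `subject_id` column,
#'   also return the subject-mean latency aggregate.
#' @return a data frame with columns `condition`, `n`, `prop_burst`,
#'   `mean_first_latency` (NA when no trial has a burst), and
#'   `mean_first_latency_subject` when requested.
#' @export
burst_stats <- function(table, correct_only = TRUE, by_subject = FALSE) {
  tab <- table[!table$omitted, , drop = FALSE]
  if (correct_only) tab <- tab[tab$accuracy %in% TRUE, , drop = FALSE]
  conds <- unique(as.character(tab$condition))
  res <- lapply(conds, function(cc) {
    sub <- tab[tab$condition == cc, , drop = FALSE]
    has <- sub$n_bursts > 0
    row <- data.frame(
      condition = cc, n = nrow(sub),
      prop_burst = if (nrow(sub)) mean(has) else 0,
      mean_first_latency = if (any(has))
        mean(sub$first_burst_latency[has]) else NA_real_,
      stringsAsFactors = FALSE)
    if (by_subject && "subject_id" %in% names(sub)) {
      per <- tapply(sub$first_burst_latency[has], sub$subject_id[has], mean)
      row$mean_first_latency_subject <-
        if (length(per)) mean(per, na.rm = TRUE) else NA_real_
    }
    row
  })
  do.call(rbind, res)
}

#' Between-trial PMT-MT correlation per condition
#'
#' Pearson correlation between premotor and motor times across trials.
#' An unfiltered model with no between-trial variability predicts a null
#' correlation (Markov property of the diffusion); filtering and drift
#' variability push it positive.
#'
#' @param table a trial table; omitted trials are excluded.
#' @param correct_only restrict to correct trials (default).
#' @return data frame with columns `condition`, `n`, `r`; `r` is `NA`
#'   (not 0) with fewer than 3 trials or degenerate variance.
#' @export
pmt_mt_correlation <- function(table, correct_only = TRUE) {
  tab <- table[!table$omitted, , drop = FALSE]
  if (correct_only) tab <- tab[tab$accuracy %in% TRUE, , drop = FALSE]
  conds <- unique(as.character(tab$condition))
  res <- lapply(conds, function(cc) {
    sub <- tab[tab$condition == cc, , drop = FALSE]
    ok <- nrow(sub) >= 3 && stats::sd(sub$pmt) > 0 && stats::sd(sub$mt) > 0
    data.frame(condition = cc, n = nrow(sub),
               r = if (ok) stats::cor(sub$pmt, sub$mt) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Mean neural drive time-locked on EMG onset
#'
#' Simulates correct trials, takes the response channel's neural drive,
#' extends it past the response threshold with a linear decay of
#' `decay` evidence-units/s (floored at 0, emulating the die-away of
#' muscular excitation after the response), aligns every trial at its
#' `t_g` (where the drive is 0 by construction), and averages pointwise.
#' The rising slope of the average over the first tens of milliseconds
#' after `t_g` tracks the underlying motor-preparation dynamics and hence
#' decreases with task difficulty.
#'
#' @inheritParams simulate_trial
#' @param n number of correct trials to accumulate (>= 1).
#' @param decay post-threshold linear decay rate, evidence-units/s.
#' @param window lag window around `t_g` (s), e.g. `c(-0.2, 0.6)`.
#' @param max_attempts simulation budget before giving up on finding
#'   `n` correct trials.
#' @return data frame with columns `lag` and `drive` (mean neural drive,
#'   evidence units; 0 at lag 0).
#' @export
mean_neural_drive <- function(params, map, condition, config = sim_config(),
                              n = 1000, value = condition,
                              correct_channel = "upper",
                              decay = 0.15, window = c(-0.2, 0.6),
                              max_attempts = 20 * n) {
  stopifnot(n >= 1)
  dt <- config$dt
  lags <- seq(window[1], window[2], by = dt)
  acc <- numeric(length(lags))
  got <- 0L
  attempts <- 0L
  cfg <- sim_config(dt, config$max_decision_time, config$min_burst_duration,
                    record_trajectories = TRUE)
  while (got < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    rec <- simulate_trial(params, map, condition, cfg, value,
                          correct_channel)
    if (rec$omitted || !isTRUE(rec$accuracy)) next
    traj <- rec$trajectory
    z <- if (rec$response == "upper") traj$zR else traj$zL
    hit_i <- traj$hit_idx + 1L                       # 1-based
    z <- z[seq_len(hit_i)]
    # linear decay after threshold attainment, floored at zero
    n_decay <- ceiling(z[hit_i] / (decay * dt))
    tail_z <- pmax(z[hit_i] - decay * dt * seq_len(n_decay), 0)
    z <- c(z, tail_z)
    tg_i <- traj$tg_idx + 1L
    # map trial samples onto the lag grid: sample j sits at lag (j - tg_i)*dt
    idx <- tg_i + as.integer(round(lags / dt))
    vals <- numeric(length(lags))                    # zero outside the trial
    inside <- idx >= 1L & idx <= length(z)
    vals[inside] <- z[idx[inside]]
    acc <- acc + vals
    got <- got + 1L
  }
  if (got == 0L) stop("no correct trials within the simulation budget")
  data.frame(lag = lags, drive = acc / got)
}
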