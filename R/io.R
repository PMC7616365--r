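#' Trial-table serialization
#'
#' Trial tables are exchanged as tab-delimited text with one row per
#' trial and a mandatory header:
#' `subject_id, condition, stimulus_class, response, accuracy, rt_ms,
#' pmt_ms, mt_ms, omitted, n_partial_bursts, first_burst_channel,
#' first_burst_latency_ms`. Times are serialized in milliseconds
#' (internal computation uses seconds); `stimulus_class` stores the
#' condition's correct channel so accuracy-coded summaries can be
#' recomputed after reading. Omitted rows have empty response and latency
#' fields. Numbers are written with full precision so a write/read round
#' trip preserves every summary.
#'
#' @param table a trial table ([simulate_dataset()]).
#' @param path output file path.
#' @param subject_id subject label, recycled over rows (used when the
#'   table has no `subject_id` column).
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path, subject_id = "s01") {
  ms <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x * 1000))
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(table)) table$subject_id
      else rep_len(subject_id, nrow(table)),
    condition = table$condition,
    stimulus_class = table$correct_channel,
    response = ifelse(is.na(table$response), "", table$response),
    accuracy = ifelse(is.na(table$accuracy), "",
                      as.integer(table$accuracy)),
    rt_ms = ms(table$rt), pmt_ms = ms(table$pmt), mt_ms = ms(table$mt),
    omitted = as.integer(table$omitted),
    n_partial_bursts = ifelse(is.na(table$n_bursts), "", table$n_bursts),
    first_burst_channel = ifelse(is.na(table$first_burst_channel), "",
                                 table$first_burst_channel),
    first_burst_latency_ms = ms(table$first_burst_latency),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param check how to treat rows violating `rt = pmt + mt` (1 ms
#'   tolerance): `"warn"` (default) or `"error"`; either way the offending
#'   row numbers are reported.
#' @return for `read_trial_table`, a trial table in internal (seconds)
#'   units with columns `subject_id`, `condition`, `correct_channel`,
#'   `response`, `accuracy`, `pmt`, `mt`, `rt`, `omitted`, `n_bursts`,
#'   `first_burst_channel`, `first_burst_latency`.
#' @export
read_trial_table <- function(path, check = c("warn", "error")) {
  check <- match.arg(check)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  schema <- c("subject_id", "condition", "stimulus_class", "response",
              "accuracy", "rt_ms", "pmt_ms", "mt_ms", "omitted",
              "n_partial_bursts", "first_burst_channel",
              "first_burst_latency_ms")
  if (!identical(names(raw), schema))
    stop("trial-table header mismatch; expected columns: ",
         paste(schema, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  tab <- data.frame(
    subject_id = raw$subject_id,
    condition = raw$condition,
    correct_channel = raw$stimulus_class,
    response = ifelse(raw$response == "", NA, raw$response),
    accuracy = ifelse(raw$accuracy == "", NA,
                      raw$accuracy %in% c("1", "TRUE")),
    pmt = num(raw$pmt_ms) / 1000, mt = num(raw$mt_ms) / 1000,
    rt = num(raw$rt_ms) / 1000,
    omitted = raw$omitted %in% c("1", "TRUE"),
    n_bursts = as.integer(num(raw$n_partial_bursts)),
    first_burst_channel = ifelse(raw$first_burst_channel == "", NA,
                                 raw$first_burst_channel),
    first_burst_latency = num(raw$first_burst_latency_ms) / 1000,
    stringsAsFactors = FALSE)
  live <- !tab$omitted
  bad <- which(live & abs(tab$rt - (tab$pmt + tab$mt)) > 0.001 + 1e-12)
  if (length(bad)) {
    msg <- paste0("rt != pmt + mt beyond 1 ms in row(s): ",
                  paste(bad, collapse = ", "))
    if (check == "error") stop(msg) else warning(msg)
  }
  tab
}

#' Write a simulated trajectory as delimited text
#'
#' Dumps the time grid and the decision, motor-preparation and
#' neural-drive paths (`t`, `x`, `y`, `zL`, `zR`) of one trial for
#' external plotting.
#'
#' @param traj a `gcdf_trajectory` from [integrate_paths()].
#' @param path output file path (tab-separated, header row).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(
    data.frame(t = traj$t, x = traj$x, y = traj$y,
               zL = traj$zL, zR = traj$zR),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize per-condition summaries as JSON
#'
#' Writes the descriptive summaries of a trial table (trial-type
#' proportions, quantile summary, burst statistics, PMT-MT correlations,
#' omission rates) as structured JSON keyed by summary then condition.
#'
#' @param table a trial table.
#' @param path output path for the JSON document.
#' @param probs quantile probabilities for the quantile summary.
#' @return the summary list, invisibly.
#' @export
write_summaries_json <- function(table, path,
                                 probs = c(.1, .3, .5, .7, .9)) {
  s <- list(
    trial_types = trial_type_proportions(table),
    quantiles = quantile_summary(table, probs),
    bursts = burst_stats(table),
    pmt_mt_correlation = pmt_mt_correlation(table),
    omission_rate = tapply(table$omitted, table$condition, mean))
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(s)
}
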