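# shared model setups for the test suite

raw_gcdf_exp1 <- function() preset_params("exp1", "GCDF", "raw")
raw_gcd_exp1 <- function() preset_params("exp1", "GCD", "raw")

# noise-free unfiltered ramp with closed-form event times
ramp_model <- function(v = 0.2) {
  list(params = gcdf_params("GCD", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1,
                            sigma = 0, sigma_free = TRUE),
       map = drift_linear(k = 1), condition = v)
}

# one-condition design helper
one_condition_design <- function(n, value = 0.2, deadline = 5,
                                 correct = "upper") {
  structure(data.frame(condition = as.character(value), value = value,
                       n_trials = as.integer(n), correct_channel = correct,
                       stringsAsFactors = FALSE),
            deadline = deadline, class = c("gcdf_design", "data.frame"))
}

# independent order-statistic quantile oracle (linear interpolation between
# closest ranks): x_(k) at p = (k-1)/(n-1)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# hand-built binned-counts object: one condition, counts laid into the
# first cells of the pureC slice
two_cell_counts <- function(n1, n2) {
  counts <- array(0L, dim = c(1, 6, 6, 6),
                  dimnames = list(condition = "c1",
                                  type = c("pureC", "CC", "IC", "pureI",
                                           "II", "CI"),
                                  pmt_bin = NULL, mt_bin = NULL))
  counts[1, 1, 1, 1] <- n1
  counts[1, 1, 2, 1] <- n2
  structure(list(counts = counts, n_i = c(c1 = n1 + n2), bins = NULL),
            class = "gcdf_binned_counts")
}
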