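#' Per-subject model-selection tally
#'
#' Counts, over subjects, which of two models attains the strictly lower
#' information criterion, and tests whether the split departs from chance
#' with an exact two-sided binomial test (p = 0.5). Ties are counted
#' separately and excluded from the test.
#'
#' @param crit_a,crit_b paired per-subject criterion values (AIC or BIC)
#'   for models A and B.
#' @param alpha significance level (default 0.05).
#' @return list with `n_a`, `n_b`, `n_ties`, `n` (non-tied subjects),
#'   `p_value`, `significant`, and `favored` (`"A"`, `"B"` or `"none"`).
#' @export
model_selection_tally <- function(crit_a, crit_b, alpha = 0.05) {
  stopifnot(length(crit_a) == length(crit_b), length(crit_a) >= 1)
  n_a <- sum(crit_a < crit_b)
  n_b <- sum(crit_b < crit_a)
  n_ties <- sum(crit_a == crit_b)
  n <- n_a + n_b
  if (n == 0)
    return(list(n_a = n_a, n_b = n_b, n_ties = n_ties, n = 0,
                p_value = 1, significant = FALSE, favored = "none"))
  p <- stats::binom.test(max(n_a, n_b), n, p = 0.5,
                         alternative = "two.sided")$p.value
  sig <- p < alpha
  list(n_a = n_a, n_b = n_b, n_ties = n_ties, n = n, p_value = p,
       significant = sig,
       favored = if (!sig || n_a == n_b) "none" else
         if (n_a > n_b) "A" else "B")
}

#' Smallest significant subject count
#'
#' The smallest number of subjects, out of `n`, that must favour one
#' model for the exact two-sided binomial test against p = 0.5 to be
#' significant at level `alpha`. For 18 subjects at the 5% level this is
#' 14.
#'
#' @param n number of subjects (>= 1).
#' @param alpha significance level.
#' @return the smallest qualifying count, or `NA` if no count up to `n`
#'   is significant.
#' @export
min_significant_count <- function(n, alpha = 0.05) {
  stopifnot(n >= 1)
  for (m in seq(ceiling(n / 2), n)) {
    p <- stats::binom.test(m, n, p = 0.5, alternative = "two.sided")$p.value
    if (p < alpha) return(as.integer(m))
  }
  NA_integer_
}
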