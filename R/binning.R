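#' Quantile bin boundaries from an observed trial table
#'
#' Boundaries for the binned fit statistic are computed once from the
#' observed data — per condition and response class (correct vs
#' incorrect), separately for PMT and MT — at the quantile probabilities
#' (.1, .3, .5, .7, .9), giving six bins per margin. They never depend on
#' simulated data. Sparse cells collapse to coarser boundaries: below
#' `min_count` trials a class gets a single bin (no cuts); between
#' `min_count` and `4 * min_count` trials only the median cut is used.
#'
#' @param observed an observed trial table; omitted trials are excluded.
#' @param probs quantile probabilities for the cuts.
#' @param min_count collapse floor (default 5).
#' @return an object of class `gcdf_bins`: nested list
#'   `boundaries[[condition]][[class]]` with elements `pmt`, `mt`
#'   (strictly the cut vectors) and `n`; plus the condition order.
#' @export
build_bins <- function(observed, probs = c(.1, .3, .5, .7, .9),
                       min_count = 5) {
  tab <- observed[!observed$omitted, , drop = FALSE]
  if (!nrow(tab)) stop("empty observed table")
  conds <- unique(as.character(tab$condition))
  boundaries <- list()
  for (cc in conds) {
    sub <- tab[tab$condition == cc, , drop = FALSE]
    if (!nrow(sub)) stop("condition with no non-omitted trials: ", cc)
    boundaries[[cc]] <- list()
    for (cls in c("correct", "incorrect")) {
      sel <- if (cls == "correct") sub$accuracy %in% TRUE else
        sub$accuracy %in% FALSE
      n <- sum(sel)
      p_use <- if (n < min_count) numeric(0) else
        if (n < 4 * min_count) 0.5 else probs
      cuts <- function(x) if (length(p_use)) empirical_quantiles(x[sel], p_use)
        else numeric(0)
      boundaries[[cc]][[cls]] <- list(pmt = cuts(sub$pmt),
                                      mt = cuts(sub$mt), n = n)
    }
  }
  structure(list(boundaries = boundaries, conditions = conds,
                 probs = probs, min_count = min_count,
                 n_bins = length(probs) + 1L),
            class = "gcdf_bins")
}

#' Bin a trial table over condition, trial type, PMT bin and MT bin
#'
#' Counts trials in every cell of the condition x trial-type x PMT-bin x
#' MT-bin cross-classification, using boundaries previously built from
#' observed data. A trial exactly on a boundary goes to the lower bin;
#' the outer bins are unbounded, so every trial is binnable. Marginal
#' totals are preserved: the cells of a condition sum to its number of
#' non-omitted trials.
#'
#' @param table a trial table; omitted trials are excluded.
#' @param bins a `gcdf_bins` object from [build_bins()].
#' @return an object of class `gcdf_binned_counts`: list with `counts`
#'   (4-d array condition x type x PMT bin x MT bin), `n_i` per-condition
#'   totals, and the `bins` used.
#' @export
bin_counts <- function(table, bins) {
  stopifnot(inherits(bins, "gcdf_bins"))
  tab <- table[!table$omitted, , drop = FALSE]
  conds <- bins$conditions
  nb <- bins$n_bins
  nt <- length(trial_type_levels)
  ci <- match(as.character(tab$condition), conds)
  if (anyNA(ci))
    stop("condition not covered by boundaries: ",
         paste(unique(tab$condition[is.na(ci)]), collapse = ", "))
  type_i <- as.integer(classify_table(tab))
  cls <- ifelse(tab$accuracy %in% TRUE, "correct", "incorrect")
  k <- integer(nrow(tab)); l <- integer(nrow(tab))
  for (ic in seq_along(conds)) {
    for (cl in c("correct", "incorrect")) {
      sel <- ci == ic & cls == cl
      if (!any(sel)) next
      b <- bins$boundaries[[conds[ic]]][[cl]]
      k[sel] <- findInterval(tab$pmt[sel], b$pmt, left.open = TRUE) + 1L
      l[sel] <- findInterval(tab$mt[sel], b$mt, left.open = TRUE) + 1L
    }
  }
  lin <- ci + length(conds) * ((type_i - 1L) + nt * ((k - 1L) + nb * (l - 1L)))
  counts <- array(tabulate(lin, nbins = length(conds) * nt * nb * nb),
                  dim = c(length(conds), nt, nb, nb),
                  dimnames = list(condition = conds,
                                  type = trial_type_levels,
                                  pmt_bin = NULL, mt_bin = NULL))
  n_i <- apply(counts, 1, sum)
  structure(list(counts = counts, n_i = n_i, bins = bins),
            class = "gcdf_binned_counts")
}

#' Likelihood-ratio chi-square statistic between binned tables
#'
#' The fit objective
#' `G2 = 2 sum n_ijkl * log( (n_ijkl / n_i) / (n'_ijkl / n'_i) )`
#' compares observed (`n`) and simulated (`n'`) proportions over the
#' condition x trial-type x PMT-bin x MT-bin cells. Cells with zero
#' observed count contribute 0. When a cell with observed mass has zero
#' simulated mass, the simulated proportion is floored at
#' `1 / (2 n'_i)` (half a trial) so the statistic stays finite; this
#' regularization never touches populated cells. The statistic depends on
#' simulated data only through proportions, so it is invariant to the
#' simulated-sample size at fixed proportions.
#'
#' @param observed,simulated `gcdf_binned_counts` with identical
#'   structure (same boundaries).
#' @return the G-squared statistic (nonnegative up to the regularization).
#' @export
g_squared <- function(observed, simulated) {
  stopifnot(inherits(observed, "gcdf_binned_counts"),
            inherits(simulated, "gcdf_binned_counts"))
  if (!identical(dim(observed$counts), dim(simulated$counts)))
    stop("structural mismatch between observed and simulated counts")
  if (any(observed$n_i == 0) || any(simulated$n_i == 0))
    stop("per-condition totals must be positive")
  n <- observed$counts
  ns <- simulated$counts
  conds <- dimnames(n)$condition
  g2 <- 0
  for (i in seq_along(conds)) {
    p <- n[i, , , ] / observed$n_i[i]
    q <- ns[i, , , ] / simulated$n_i[i]
    pos <- n[i, , , ] > 0
    q[pos & q == 0] <- 1 / (2 * simulated$n_i[i])
    g2 <- g2 + 2 * sum(n[i, , , ][pos] * log(p[pos] / q[pos]))
  }
  g2
}

#' Information criteria from a G-squared value
#'
#' `AIC = G2 + 2 m` and `BIC = G2 + m log(N)` (natural log), where `m` is
#' the number of free parameters and `N` the number of observations that
#' entered the statistic.
#'
#' @param g2 G-squared value.
#' @param m number of free parameters (>= 0).
#' @param N number of observations (>= 1).
#' @return named vector `c(AIC = , BIC = )`.
#' @export
information_criteria <- function(g2, m, N) {
  stopifnot(m >= 0, N >= 1)
  c(AIC = g2 + 2 * m, BIC = g2 + m * log(N))
}
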