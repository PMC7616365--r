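# binning, the G-squared objective, information criteria, differential
# evolution fitting, and the model-selection machinery

test_that("bin boundaries come from observed quantiles and collapse when sparse", {
  set.seed(6)
  n <- 100
  tab <- data.frame(condition = "c1", value = NA_real_, trial = 1:n,
                    seed = 1:n, correct_channel = "upper",
                    response = "upper", accuracy = TRUE,
                    tg = 0.2, decision_time = 0.3,
                    pmt = stats::runif(n), mt = stats::runif(n),
                    rt = NA_real_, n_bursts = 0L,
                    first_burst_channel = NA_character_,
                    first_burst_latency = NA_real_, omitted = FALSE,
                    stringsAsFactors = FALSE)
  tab$rt <- tab$pmt + tab$mt
  bins <- build_bins(tab)
  cuts <- bins$boundaries$c1$correct$pmt
  expect_length(cuts, 5)
  # order-statistic oracle: cuts are the sample quantiles, near (.1,...,.9)
  expect_equal(cuts, vapply(c(.1, .3, .5, .7, .9),
                            function(p) quantile_oracle(tab$pmt, p),
                            numeric(1)))
  expect_true(all(abs(cuts - c(.1, .3, .5, .7, .9)) < 0.12))
  # 4 trials with floor 5: single bin, no cuts
  bins4 <- build_bins(tab[1:4, ], min_count = 5)
  expect_length(bins4$boundaries$c1$correct$pmt, 0)
  # boundaries depend only on observations, not on any simulated table
  expect_identical(build_bins(tab)$boundaries, bins$boundaries)
})

test_that("binned counts conserve totals, respect ties, ignore order", {
  fx <- degenerate_fixtures()
  tab <- fx$tie_table
  bins <- build_bins(tab, min_count = 1)
  bc <- bin_counts(tab, bins)
  expect_identical(sum(bc$counts), nrow(tab))
  expect_identical(unname(bc$n_i["c1"]), nrow(tab))
  # single trial: exactly one nonzero cell
  bc1 <- bin_counts(tab[3, ], bins)
  expect_identical(sum(bc1$counts > 0), 1L)
  # permuting trials leaves the counts unchanged
  bc_perm <- bin_counts(tab[sample(nrow(tab)), ], bins)
  expect_identical(bc$counts, bc_perm$counts)
  # tie rule: a value exactly on a cut goes to the lower bin
  cuts <- bins$boundaries$c1$correct$pmt
  one <- tab[3, ]
  one$pmt <- cuts[2]
  bco <- bin_counts(one, bins)
  k <- which(apply(bco$counts, 3, sum) > 0)
  expect_identical(k, 2L)
})

test_that("G-squared: hand value, zero at equality, proportion invariance", {
  obs <- two_cell_counts(60, 40)
  sim_eq <- two_cell_counts(600, 400)
  expect_equal(g_squared(obs, sim_eq), 0)
  sim_5050 <- two_cell_counts(500, 500)
  hand <- 2 * (60 * log(0.6 / 0.5) + 40 * log(0.4 / 0.5))
  expect_equal(g_squared(obs, sim_5050), hand)
  expect_equal(g_squared(obs, sim_5050), 4.027, tolerance = 1e-3)
  # doubling simulated counts at fixed proportions changes nothing
  expect_equal(g_squared(obs, two_cell_counts(1000, 1000)),
               g_squared(obs, sim_5050))
  # a zero-simulated cell with observed mass is floored, not infinite
  sim_zero <- two_cell_counts(1000, 0)
  g <- g_squared(obs, sim_zero)
  expect_true(is.finite(g) && g > 0)
  # structural mismatch errors
  obs2 <- two_cell_counts(60, 40)
  obs2$counts <- obs2$counts[, , 1:3, , drop = FALSE]
  expect_error(g_squared(obs2, sim_5050), "mismatch")
})

test_that("information criteria are the stated arithmetic identities", {
  ic <- information_criteria(100, 6, 1000)
  expect_equal(unname(ic["AIC"]), 112)
  expect_equal(unname(ic["BIC"]), 100 + 6 * log(1000))
  expect_equal(information_criteria(50, 0, 10), c(AIC = 50, BIC = 50))
  ic2 <- information_criteria(10, 1, exp(2))
  expect_equal(unname(ic2["BIC"] - 10), 2)
})

test_that("model-selection tally and the exact binomial cutoff", {
  # 16 of 18 favour model A: significant
  t16 <- model_selection_tally(1:18, 1:18 + c(rep(1, 16), rep(-1, 2)))
  expect_identical(t16$n_a, 16L)
  expect_true(t16$significant)
  expect_identical(t16$favored, "A")
  # 13 of 18: exact two-sided p ~ 0.096, not significant
  t13 <- model_selection_tally(1:18, 1:18 + c(rep(1, 13), rep(-1, 5)))
  expect_false(t13$significant)
  expect_equal(t13$p_value, 0.0963, tolerance = 1e-3)
  # 9 of 18: symmetric split, p = 1
  t9 <- model_selection_tally(1:18, 1:18 + rep(c(1, -1), 9))
  expect_equal(t9$p_value, 1)
  expect_identical(t9$favored, "none")
  # ties are excluded from the test n
  tt <- model_selection_tally(c(1, 2, 3), c(1, 5, 6))
  expect_identical(tt$n_ties, 1L)
  expect_identical(tt$n, 2L)

  expect_identical(min_significant_count(18), 14L)
  expect_true(is.na(min_significant_count(1)))
  # exhaustive two-sided tail enumeration oracle for n = 24
  n <- 24
  two_sided_p <- function(m) {
    d <- stats::dbinom(0:n, n, 0.5)
    sum(d[d <= d[m + 1] + 1e-12])
  }
  ps <- vapply(0:n, two_sided_p, numeric(1))
  oracle <- min((0:n)[ps < 0.05 & 0:n >= ceiling(n / 2)])
  expect_identical(min_significant_count(24), as.integer(oracle))
})

test_that("fitting is deterministic and honours its contracts", {
  pp <- raw_gcd_exp1()
  des <- one_condition_design(60, value = 0.2)
  obs <- simulate_dataset(pp$params, pp$map, des, seed = 3)
  spec <- spec_linear_coherence("GCD", raw = TRUE)
  fit1 <- fit_model(obs, spec, des, n_sim = 150, n_pop = 6, n_gen = 2,
                    seed = 10)
  fit2 <- fit_model(obs, spec, des, n_sim = 150, n_pop = 6, n_gen = 2,
                    seed = 10)
  expect_identical(fit1$par, fit2$par)
  expect_identical(fit1$g2, fit2$g2)
  expect_identical(fit1$trace, fit2$trace)
  # criteria are recomputable from the stored fields
  expect_equal(fit1$AIC - fit1$g2, 2 * fit1$m)
  expect_equal(fit1$BIC - fit1$g2, fit1$m * log(fit1$N))
  expect_identical(fit1$N, sum(!obs$omitted))
  # a table missing a design condition is rejected by name
  des2 <- make_design("exp1", n_trials = 10)
  expect_error(fit_model(obs, spec, des2, n_sim = 50, n_gen = 1, seed = 1),
               "0.4")
  expect_error(fit_model(obs, spec, des, n_sim = 0, n_gen = 1, seed = 1),
               "budget")
})

test_that("the objective dips at the generating drift slope", {
  pp <- raw_gcdf_exp1()
  des <- make_design("exp1", n_trials = 96)
  obs <- simulate_dataset(pp$params, pp$map, des, seed = 41)
  bins <- build_bins(obs)
  oc <- bin_counts(obs, bins)
  sim_des <- make_design("exp1", n_trials = 2000)
  eval_k <- function(k) {
    par <- gcdf_params("GCDF", g = 0.069, r = 0.022, Te = 0.283,
                       Tr = 0.093, lambda = 21.471)
    sim <- simulate_dataset(par, drift_linear(k), sim_des, seed = 55)
    g_squared(oc, bin_counts(sim, bins))
  }
  ks <- c(0.6, 0.9, 1.183, 1.5, 1.8)
  g2s <- vapply(ks, eval_k, numeric(1))
  expect_lte(which.min(g2s), 4L)  # minimum at truth or one grid step away
  expect_gte(which.min(g2s), 2L)
})
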