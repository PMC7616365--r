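# trajectory integration, event extraction, and trial/dataset simulation

test_that("noise-free integration follows the drift ramp exactly", {
  m <- ramp_model(v = 0.2)
  rp <- structure(list(v = 0.2, x0 = 0, Te = 0.3, Tr = 0.1, lambda = Inf),
                  class = "gcdf_trial_params")
  tr <- integrate_paths(rp, m$params, sim_config(), stop_at_threshold = FALSE)
  expect_equal(tr$x, 0.2 * tr$t, tolerance = 1e-10)
  expect_identical(tr$x, tr$y)  # unfiltered: y is x
})

test_that("C++ Euler filter matches an independent R recursion exactly", {
  p <- gcdf_params("GCDF", g = 100, r = 100, Te = 0, Tr = 0, lambda = 20)
  rp <- structure(list(v = 0.5, x0 = 0.02, Te = 0, Tr = 0, lambda = 20),
                  class = "gcdf_trial_params")
  set.seed(11)
  tr <- integrate_paths(rp, p, sim_config(max_decision_time = 1),
                        stop_at_threshold = FALSE)
  # independent reimplementation of the update rule on the recorded x-path
  y <- numeric(length(tr$x))
  y[1] <- 0.02
  a <- 20 * 0.001
  for (n in 2:length(y)) y[n] <- y[n - 1] + a * (tr$x[n] - y[n - 1])
  expect_equal(tr$y, y, tolerance = 1e-12)
})

test_that("filtered path equals the exponential-kernel convolution to O(dt)", {
  for (lam in c(20, 60)) {
    p <- gcdf_params("GCDF", g = 100, r = 100, Te = 0, Tr = 0, lambda = lam)
    rp <- structure(list(v = 0.5, x0 = 0, Te = 0, Tr = 0, lambda = lam),
                    class = "gcdf_trial_params")
    set.seed(5)
    tr <- integrate_paths(rp, p, sim_config(max_decision_time = 2),
                          stop_at_threshold = FALSE)
    dt <- 0.001
    ex <- exp(lam * tr$t)
    s <- cumsum(ex * tr$x) - ex[1] * tr$x[1]   # right Riemann, j = 1..n
    y_conv <- lam * dt * s / ex
    rel <- max(abs(tr$y - y_conv)) / max(abs(tr$y))
    expect_lt(rel, 2 * lam * dt)
  }
})

test_that("noise-free event chain: t_g = g/v, hit = (g+r)/v, one grid step", {
  m <- ramp_model(v = 0.2)
  rp <- structure(list(v = 0.2, x0 = 0, Te = 0.3, Tr = 0.1, lambda = Inf),
                  class = "gcdf_trial_params")
  tr <- integrate_paths(rp, m$params, sim_config())
  ev <- extract_events(tr, g = 0.05, r = 0.02)
  expect_false(ev$omitted)
  expect_lt(abs(ev$tg - 0.250), 0.0011)
  expect_lt(abs(ev$hit_time - 0.350), 0.0011)
  expect_identical(ev$channel, "upper")
  expect_identical(nrow(ev$bursts), 0L)
})

test_that("a dip below the gate before threshold yields one partial burst", {
  fx <- degenerate_fixtures()$burst_trajectory
  ev <- extract_events(fx, g = fx$g, r = fx$r)
  expect_false(ev$omitted)
  expect_identical(nrow(ev$bursts), 1L)
  expect_identical(ev$bursts$channel, "upper")
  expect_identical(ev$channel, "upper")
  # t_g is the start of the *final* excursion, after the dip
  expect_gt(ev$tg, max(ev$bursts$onset))
})

test_that("R event extraction agrees with the C++ fast path per trial", {
  pp <- raw_gcdf_exp1()
  des <- one_condition_design(50, value = 0.08)
  tab <- simulate_dataset(pp$params, pp$map, des, seed = 77)
  for (i in c(1, 7, 23, 50)) {
    set.seed(tab$seed[i])
    rec <- simulate_trial(pp$params, pp$map, "0.08", sim_config(),
                          value = 0.08, correct_channel = "upper")
    expect_identical(rec$omitted, tab$omitted[i])
    if (!rec$omitted) {
      expect_identical(rec$pmt, tab$pmt[i])
      expect_identical(rec$mt, tab$mt[i])
      expect_identical(rec$response, tab$response[i])
      expect_identical(nrow(rec$bursts), as.integer(tab$n_bursts[i]))
      if (nrow(rec$bursts) > 0)
        expect_identical(rec$bursts$onset[1], tab$first_burst_latency[i])
    }
  }
})

test_that("closed-form trial chain and determinism of simulate_trial", {
  m <- ramp_model(v = 0.2)
  set.seed(1)
  rec <- simulate_trial(m$params, m$map, 0.2, correct_channel = "upper")
  expect_lt(abs(rec$pmt - 0.550), 0.0011)
  expect_lt(abs(rec$mt - 0.200), 0.0021)
  expect_lt(abs(rec$rt - 0.750), 0.0021)
  expect_identical(rec$rt, rec$pmt + rec$mt)
  set.seed(1)
  rec2 <- simulate_trial(m$params, m$map, 0.2, correct_channel = "upper")
  expect_identical(rec, rec2)
})

test_that("zero drift splits responses evenly and RT adds up", {
  p <- raw_gcd_exp1()
  des <- one_condition_design(4000, value = 0)
  tab <- simulate_dataset(p$params, p$map, des, seed = 31)
  live <- tab[!tab$omitted, ]
  expect_identical(live$rt, live$pmt + live$mt)
  prop_upper <- mean(live$response == "upper")
  expect_lt(abs(prop_upper - 0.5), 3 * 0.5 / sqrt(nrow(live)))
})

test_that("mutual exclusivity of the two neural-drive channels", {
  pp <- raw_gcdf_exp1()
  set.seed(13)
  for (i in 1:5) {
    rp <- sample_trial_params(pp$params, pp$map, 0.05)
    tr <- integrate_paths(rp, pp$params, sim_config())
    expect_true(all(tr$zL * tr$zR == 0))
    expect_true(all(tr$zL >= 0 & tr$zR >= 0))
  }
})

test_that("per-condition counts, omission logging, and trial-seed provenance", {
  pp <- raw_gcdf_exp1()
  des <- make_design("exp1", n_trials = 30)
  tab <- simulate_dataset(pp$params, pp$map, des, seed = 5)
  expect_identical(nrow(tab), 180L)
  expect_identical(as.vector(table(tab$condition)[des$condition]),
                   rep(30L, 6))
  expect_named(attr(tab, "omission_rate"))
  expect_error(simulate_dataset(pp$params, pp$map, des[0, ], seed = 1),
               "empty design")
  # any single trial is regenerable from its recorded seed
  i <- 100
  set.seed(tab$seed[i])
  rec <- simulate_trial(pp$params, pp$map, tab$condition[i], sim_config(),
                        value = tab$value[i], correct_channel = "upper")
  expect_identical(rec$pmt, tab$pmt[i])
})

test_that("evidence-unit rescaling by 2 leaves every trial outcome unchanged", {
  base <- gcdf_params("GCDF", g = 0.069, r = 0.022, Te = 0.283, Tr = 0.093,
                      lambda = 21.471, sv = 0.117, sx0 = 0.074,
                      sigma = 0.1, sigma_free = TRUE)
  scaled <- gcdf_params("GCDF", g = 2 * 0.069, r = 2 * 0.022, Te = 0.283,
                        Tr = 0.093, lambda = 21.471, sv = 2 * 0.117,
                        sx0 = 2 * 0.074, sigma = 0.2, sigma_free = TRUE)
  des <- one_condition_design(2000, value = 0.12)
  t1 <- simulate_dataset(base, drift_linear(1.183), des, seed = 8)
  t2 <- simulate_dataset(scaled, drift_linear(2 * 1.183), des, seed = 8)
  expect_identical(t1$response, t2$response)
  expect_identical(t1$pmt, t2$pmt)
  expect_identical(t1$mt, t2$mt)
  expect_identical(t1$n_bursts, t2$n_bursts)
})

test_that("an infinitely leaky filter is exactly the unfiltered model", {
  gcd <- gcdf_params("GCD", g = 0.069, r = 0.022, Te = 0.283, Tr = 0.093)
  gcdf_inf <- gcdf_params("GCDF", g = 0.069, r = 0.022, Te = 0.283,
                          Tr = 0.093, lambda = Inf)
  des <- one_condition_design(500, value = 0.12)
  map <- drift_linear(1.183)
  t1 <- simulate_dataset(gcd, map, des, seed = 21)
  t2 <- simulate_dataset(gcdf_inf, map, des, seed = 21)
  expect_identical(t1$pmt, t2$pmt)
  expect_identical(t1$mt, t2$mt)
  expect_identical(t1$response, t2$response)
})

test_that("a very fast finite filter reproduces unfiltered premotor times", {
  gcd <- gcdf_params("GCD", g = 0.069, r = 0.022, Te = 0.283, Tr = 0.093)
  fast <- gcdf_params("GCDF", g = 0.069, r = 0.022, Te = 0.283, Tr = 0.093,
                      lambda = 1e6)
  des <- one_condition_design(2000, value = 0.2)
  map <- drift_linear(1.183)
  t1 <- simulate_dataset(gcd, map, des, seed = 9)
  t2 <- simulate_dataset(fast, map, des, seed = 9)
  ok <- !t1$omitted & !t2$omitted
  agree <- mean(abs(t1$pmt[ok] - t2$pmt[ok]) <= 0.002 + 1e-12)
  expect_gte(agree, 0.99)
})

test_that("Kalman-Bucy variant runs and nests the plain filter at xi = 0", {
  kb0 <- gcdf_params("GCDF_KB", g = 0.069, r = 0.022, Te = 0.283,
                     Tr = 0.093, lambda = 21.471, xi = 0)
  des <- one_condition_design(300, value = 0.2)
  map <- drift_linear(1.183)
  tkb <- simulate_dataset(kb0, map, des, seed = 14)
  # with xi = 0 and the gain near its asymptote the two variants should
  # produce very similar premotor times on matched noise
  plain <- gcdf_params("GCDF", g = 0.069, r = 0.022, Te = 0.283,
                       Tr = 0.093, lambda = 21.471)
  tpl <- simulate_dataset(plain, map, des, seed = 14)
  ok <- !tkb$omitted & !tpl$omitted
  expect_gt(stats::cor(tkb$pmt[ok], tpl$pmt[ok]), 0.95)
  # and with xi > 0 it still returns a well-formed table
  kb <- gcdf_params("GCDF_KB", g = 0.069, r = 0.022, Te = 0.283,
                    Tr = 0.093, lambda = 21.471, xi = 0.05)
  tkb2 <- simulate_dataset(kb, map, des, seed = 14)
  live <- tkb2[!tkb2$omitted, ]
  expect_identical(live$rt, live$pmt + live$mt)
})
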