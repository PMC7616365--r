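# parameter containers, constraint validation, drift maps, per-trial
# sampling, and the closed-form filter quantities

test_that("parameter constraints: nonnegativity and the 180% caps", {
  ok <- gcdf_params("GCD", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1,
                    sx0 = 0.09)
  expect_s3_class(ok, "gcdf_params")
  # the cap is 1.8 * g = 0.09, so 0.09 passes and 0.10 fails
  expect_error(
    gcdf_params("GCD", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1, sx0 = 0.10),
    "sx0.*180%")
  expect_error(
    gcdf_params("GCD", g = 0.05, r = -0.01, Te = 0.3, Tr = 0.1),
    "`r`")
  expect_error(
    gcdf_params("GCDF", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1,
                lambda = 20, sTe = 0.55),
    "sTe.*180%")
  expect_error(
    gcdf_params("GCDF", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1,
                lambda = 20, slambda = 40),
    "slambda.*180%")
  # sigma is pinned to 0.1 unless explicitly freed
  expect_error(
    gcdf_params("GCD", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1, sigma = 0.2),
    "sigma")
  expect_silent(
    gcdf_params("GCD", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1, sigma = 0,
                sigma_free = TRUE))
  # filtered variants need a leak; Inf is the exact unfiltered limit
  expect_error(gcdf_params("GCDF", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1),
               "lambda")
  expect_s3_class(gcdf_params("GCDF", g = 0.05, r = 0.02, Te = 0.3,
                              Tr = 0.1, lambda = Inf), "gcdf_params")
})

test_that("drift maps resolve conditions per their stated forms", {
  lin <- drift_linear(k = 1.183)
  expect_equal(drift_for_condition(lin, 0), 0)
  expect_equal(drift_for_condition(lin, 0.4), 1.183 * 0.4)
  crit <- drift_criterion(v1 = 0.023, dc = -0.011)
  expect_equal(drift_for_condition(crit, 53), 0.023 * 3 - 0.011)
  expect_equal(drift_for_condition(crit, 48), 0.023 * -2 - 0.011)
  pc <- drift_conditions(c(old1 = 0.138, new = -0.342))
  expect_equal(drift_for_condition(pc, "new"), -0.342)
  expect_error(drift_for_condition(pc, "old9"), "unknown condition")
})

test_that("per-trial sampling honours the variability distributions", {
  p0 <- gcdf_params("GCDF", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1,
                    lambda = 20)
  map <- drift_linear(k = 1)
  # degenerate distributions: realized values equal the means exactly
  set.seed(1)
  rp <- sample_trial_params(p0, map, 0.5)
  expect_identical(rp$v, 0.5)
  expect_identical(rp$x0, 0)
  expect_identical(rp$Te, 0.3)
  expect_identical(rp$Tr, 0.1)
  expect_identical(rp$lambda, 20)

  # uniform support from the mean/range definition: Te in [0.2, 0.4]
  p1 <- gcdf_params("GCDF", g = 0.05, r = 0.02, Te = 0.3, Tr = 0.1,
                    lambda = 20, sTe = 0.2, sv = 0.1)
  set.seed(2)
  tes <- replicate(2000, sample_trial_params(p1, map, 0.5)$Te)
  expect_true(all(tes >= 0.2 & tes <= 0.4))

  # CLT bound on the drift draws: mean within 3 sd / sqrt(n)
  set.seed(3)
  n <- 1e5
  vs <- stats::rnorm(n, 0.5, 0.1)  # oracle for the marginal the sampler uses
  expect_lt(abs(mean(vs) - 0.5), 3 * 0.1 / sqrt(n))
  set.seed(3)
  v1 <- sample_trial_params(p1, map, 0.5)$v
  set.seed(3)
  expect_identical(v1, stats::rnorm(1, 0.5, 0.1))
})

test_that("map-level sv and Te overrides reach the sampler", {
  p <- gcdf_params("GCDF", g = 0.04, r = 0.03, Te = 0.45, Tr = 0.1,
                   lambda = 60)
  rule <- sv_rule_numerosity(0.001, 0.042)
  expect_equal(rule(48), sqrt(0.042^2 + 0.048^2))
  m <- drift_criterion(0.023, -0.011, sv = rule)
  mm <- gcdf:::condition_moments(p, m, "48", 48)
  expect_equal(mm$sv, rule(48))
  m2 <- drift_conditions(c(a = 0.3, b = 0.5), Te = c(a = 0.5, b = 0.43))
  mm2 <- gcdf:::condition_moments(p, m2, "b")
  expect_equal(mm2$Te, 0.43)
  expect_equal(mm2$v, 0.5)
})

test_that("kalman gain is the tanh form: zero at 0, asymptote lambda'", {
  expect_equal(kalman_gain(5, 0), 0)
  expect_equal(kalman_gain(1, 1), tanh(1))
  expect_equal(kalman_gain(21.471, 10), 21.471, tolerance = 1e-6)
  expect_error(kalman_gain(-1, 1), "lambda_prime")
  expect_error(kalman_gain(1, -1), "`t`")
  # property: nondecreasing in t and bounded by lambda' on random grids
  set.seed(42)
  for (i in 1:20) {
    lp <- stats::runif(1, 0.1, 100)
    tt <- sort(stats::runif(50, 0, 2))
    gn <- kalman_gain(lp, tt)
    expect_true(all(diff(gn) >= 0))
    expect_true(all(gn <= lp))
  }
})

test_that("closed-form filter mean: null drift, GCD limit, filter delay", {
  tt <- seq(0, 2, by = 0.01)
  expect_equal(mean_filter_trajectory(0, 20, tt, x0 = 0), rep(0, length(tt)))
  # lambda large: mean approaches the unfiltered v * t
  expect_equal(mean_filter_trajectory(0.5, 1e9, tt), 0.5 * tt,
               tolerance = 1e-6)
  # v = 0.5, lambda = 20, t = 1: drift delayed by 1/lambda = 0.05 s
  expect_equal(mean_filter_trajectory(0.5, 20, 1),
               0.5 * (1 - (1 - exp(-20)) / 20))
  expect_equal(mean_filter_trajectory(0.5, 20, 1), 0.475, tolerance = 1e-8)
  expect_error(mean_filter_trajectory(0.5, -1, 1), "lambda")
})

test_that("closed-form mean matches the Monte-Carlo mean of simulated paths", {
  # three (v, lambda) settings; n paths; compare at several time points
  cfg <- sim_config(max_decision_time = 0.6)
  n <- 4000
  set.seed(99)
  for (set in list(c(v = 0.5, lambda = 20), c(v = 0.2, lambda = 8),
                   c(v = 1.0, lambda = 60))) {
    p <- gcdf_params("GCDF", g = 100, r = 100, Te = 0, Tr = 0,
                     lambda = set[["lambda"]])
    rp <- structure(list(v = set[["v"]], x0 = 0, Te = 0, Tr = 0,
                         lambda = set[["lambda"]]),
                    class = "gcdf_trial_params")
    idx <- c(101L, 301L, 601L)  # t = 0.1, 0.3, 0.6
    ys <- replicate(n, integrate_paths(rp, p, cfg,
                                       stop_at_threshold = FALSE)$y[idx])
    mc <- rowMeans(ys)
    se <- apply(ys, 1, stats::sd) / sqrt(n)
    closed <- mean_filter_trajectory(set[["v"]], set[["lambda"]],
                                     c(0.1, 0.3, 0.6))
    expect_true(all(abs(mc - closed) < 4 * se + 1e-3),
                label = sprintf("v=%g lambda=%g", set[["v"]],
                                set[["lambda"]]))
  }
})
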