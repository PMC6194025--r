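test_that("extract_extrema finds sine peaks and troughs, plateaus count once", {
  t <- seq(0, 100, by = 0.1)
  ts <- time_series(sin(2 * pi * t / 10), dt = 0.1)
  ex <- extract_extrema(ts)
  expect_equal(length(ex$maxima), 10, tolerance = 1)
  expect_true(all(abs(ex$maxima - 1) < 1e-3))
  expect_true(all(abs(ex$minima + 1) < 1e-3))
  # trapezoid with flat tops: each plateau is a single maximum
  trap <- rep(c(0, 1, 1, 1, 0, -1, -1, -1), times = 5)
  ex2 <- extract_extrema(time_series(trap, dt = 1))
  expect_equal(length(ex2$maxima), length(ex2$minima), tolerance = 1)
  expect_true(all(ex2$maxima == 1))
  expect_error(extract_extrema(time_series(c(1, 2), dt = 1)), "3 samples")
})

test_that("distinct_values merges within tolerance and splits across it", {
  x <- c(1.000, 1.001, 1.002, 2.000, 2.001, 5)
  got <- distinct_values(x, tol = 0.005, scale = 4)
  expect_length(got, 3)
  expect_equal(got, c(1.001, 2.0005, 5))
  # everything within one cluster
  expect_length(distinct_values(c(1, 1.0001, 1.0002), tol = 0.005, scale = 1), 1)
  expect_identical(distinct_values(numeric(0)), numeric(0))
  # zero spread collapses to the mean
  expect_equal(distinct_values(rep(3, 5)), 3)
})

test_that("classify_regime covers fixed points, period-k and complex", {
  expect_equal(classify_regime(numeric(0), numeric(0)), "fixed_point")
  expect_equal(classify_regime(1, 0.5, steady_state = TRUE), "fixed_point")
  expect_equal(classify_regime(1.0000001, 1, amplitude_floor = 1e-3),
               "fixed_point")
  expect_equal(classify_regime(1, -1), "period_1")
  expect_equal(classify_regime(c(1, 2), c(-1, -2)), "period_2")
  expect_equal(classify_regime(seq_len(40), -seq_len(40), k_max = 32),
               "complex")
  # map semantics: the distinct orbit values give the cycle length,
  # and a map fixed point is a period-1 orbit
  expect_equal(classify_regime(0.6, 0.6, is_discrete = TRUE), "period_1")
  expect_equal(classify_regime(c(0.5, 0.8), c(0.5, 0.8), is_discrete = TRUE),
               "period_2")
  expect_equal(classify_regime(seq_len(40), seq_len(40), k_max = 32,
                               is_discrete = TRUE), "complex")
})

test_that("logistic sweep labels known windows and matches a brute-force oracle", {
  cfg <- simulation_config(duration = 400, dt_out = 1, transient = 1000)
  grid <- c(2.9, 3.2, 3.5)
  bd <- bifurcation_sweep(
    function(r) builtin_system("logistic_map", list(r = r)),
    "r", grid, observed_variable = "x", config = cfg, initial_state = 0.1)
  expect_equal(bd$regime_labels, c("period_1", "period_2", "period_4"))
  # brute-force oracle: count distinct values of the settled orbit
  oracle_k <- vapply(grid, function(r) {
    x <- 0.1
    for (k in 1:1400) x <- r * x * (1 - x)
    orbit <- numeric(64)
    for (i in 1:64) { x <- r * x * (1 - x); orbit[i] <- x }
    length(unique(round(orbit, 6)))
  }, numeric(1))
  expect_equal(oracle_k, c(1, 2, 4))
  # known period-2 values at r = 3.2
  m32 <- sort(bd$maxima_sets[[2]])
  expect_equal(m32, c(0.5130, 0.7995), tolerance = 1e-3)
})

test_that("a flow sweep separates fixed points from limit cycles", {
  # Brusselator: Hopf at B = 1 + A^2; A = 0.4 -> B* = 1.16
  cfg <- simulation_config(duration = 400, dt_out = 0.25, transient = 200)
  grid <- c(1.0, 1.1, 1.3, 1.4)
  bd <- bifurcation_sweep(
    function(B) builtin_system("forced_brusselator", list(B = B)),
    "B", grid, observed_variable = "x", config = cfg)
  expect_equal(bd$regime_labels,
               c("fixed_point", "fixed_point", "period_1", "period_1"))
})

test_that("a failing grid point is recorded as NA and does not abort the sweep", {
  cfg <- simulation_config(duration = 100, dt_out = 1, transient = 10)
  # x0 = 1.5 escapes to -Inf for the logistic map at high r
  bd <- bifurcation_sweep(
    function(r) builtin_system("logistic_map", list(r = r)),
    "r", c(3.2, 4.5), observed_variable = "x", config = cfg,
    initial_state = function(r) if (r > 4.2) 1.5 else 0.1)
  expect_equal(bd$regime_labels[1], "period_2")
  expect_true(is.na(bd$regime_labels[2]))
  expect_match(bd$errors[2], "diverged")
})

test_that("as.data.frame gives the long plotting format", {
  cfg <- simulation_config(duration = 200, dt_out = 1, transient = 500)
  bd <- bifurcation_sweep(
    function(r) builtin_system("logistic_map", list(r = r)),
    "r", c(3.2), observed_variable = "x", config = cfg, initial_state = 0.1)
  df <- as.data.frame(bd)
  expect_named(df, c("parameter_value", "extremum_type", "value", "regime"))
  expect_true(all(df$parameter_value == 3.2))
  expect_true(all(df$regime == "period_2"))
})
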