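test_that("output grid: floor(duration/dt_out) + 1 samples starting at the transient", {
  sn <- builtin_system("sinusoid")
  for (dur in c(100, 123.4, 250)) {
    cfg <- simulation_config(duration = dur, dt_out = 0.7, transient = 11)
    ts <- integrate_system(sn, NULL, cfg)
    expect_equal(nrow(ts$values), floor(dur / 0.7) + 1L)
    expect_equal(ts$t_start, 11)
    expect_equal(ts$dt, 0.7)
  }
})

test_that("transient discard leaves the trajectory itself unchanged", {
  sn <- builtin_system("sinusoid", list(amplitude = 1, period = 30))
  long <- integrate_system(sn, NULL,
                           simulation_config(duration = 180, dt_out = 0.5))
  cut <- integrate_system(sn, NULL,
                          simulation_config(duration = 120, dt_out = 0.5,
                                            transient = 60))
  # samples at the same absolute times must agree
  i_long <- match(ts_times(cut), ts_times(long))
  expect_false(anyNA(i_long))
  expect_equal(cut$values, long$values[i_long, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("the flow integrator matches the analytic sinusoid", {
  sn <- builtin_system("sinusoid", list(amplitude = 2, period = 12))
  cfg <- simulation_config(duration = 100, dt_out = 0.25, transient = 7)
  ts <- integrate_system(sn, NULL, cfg)
  expect_equal(ts_variable(ts, "x"), 2 * sin(2 * pi * ts_times(ts) / 12),
               tolerance = 1e-6)
})

test_that("discrete maps iterate exactly, with transient-step discard", {
  lm <- builtin_system("logistic_map", list(r = 3.7))
  cfg <- simulation_config(duration = 50, dt_out = 1, transient = 20)
  ts <- integrate_system(lm, 0.4, cfg)
  # brute-force oracle
  x <- 0.4
  for (k in 1:20) x <- 3.7 * x * (1 - x)
  orbit <- numeric(51)
  orbit[1] <- x
  for (i in 2:51) { x <- 3.7 * x * (1 - x); orbit[i] <- x }
  expect_equal(ts_variable(ts), orbit, tolerance = 0)
  expect_true(all(ts_variable(ts) >= 0 & ts_variable(ts) <= 1))
})

test_that("a diverging trajectory raises an informative error", {
  explode <- dynamical_system("explode", "x",
                              function(state, t, parameters) state^2,
                              default_state = 1)
  cfg <- simulation_config(duration = 5, dt_out = 0.1)
  expect_error(suppressWarnings(integrate_system(explode, 1, cfg)),
               "explode|blew up|failed")
})

test_that("initial-state handling: defaults, overrides, dimension check", {
  ros <- builtin_system("rossler")
  cfg <- simulation_config(duration = 5, dt_out = 0.5)
  expect_silent(integrate_system(ros, NULL, cfg))
  expect_error(integrate_system(ros, c(1, 2), cfg), "dimension")
  nodef <- dynamical_system("nodef", "x",
                            function(state, t, parameters) -state)
  expect_error(integrate_system(nodef, NULL, cfg), "initial state")
})

test_that("detect_steady_state applies the derivative-magnitude criterion", {
  damped <- damped_linear(0.5)
  expect_true(detect_steady_state(damped, c(0, 0)))
  expect_false(detect_steady_state(damped, c(1, 0)))
  # for maps the criterion is on the displacement f(x) - x
  lm <- builtin_system("logistic_map", list(r = 2.5))
  xstar <- 1 - 1 / 2.5
  expect_true(detect_steady_state(lm, xstar, epsilon = 1e-9))
  expect_false(detect_steady_state(lm, 0.2, epsilon = 1e-9))
})

test_that("simulation_config validates its fields", {
  expect_error(simulation_config(duration = -1, dt_out = 1), "duration")
  expect_error(simulation_config(duration = 1, dt_out = 0), "dt_out")
  expect_error(simulation_config(duration = 1, dt_out = 1, transient = -2),
               "transient")
})
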