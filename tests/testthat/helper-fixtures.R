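# Shared, lazily computed fixtures. Every generator is deterministic
# (fixed initial conditions, no RNG), so caching only saves time and
# cannot couple tests.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, make(), envir = .fixtures)
  }
  get(key, envir = .fixtures, inherits = FALSE)
}

# Roessler x-component: 5001 samples at dt = 0.1 past a 50-unit transient.
rossler_x <- function() cached("rossler_x", function() {
  ts <- integrate_system(
    builtin_system("rossler"), NULL,
    simulation_config(duration = 500, dt_out = 0.1, transient = 50))
  ts_variable(ts, "x")
})

# Pure sinusoid, period 30, sampled at dt = 2 (15 samples per period:
# moderate sampling keeps the binned-AMI first minimum at the quarter
# period; see the methods vignette).
sinusoid_x <- function() cached("sinusoid_x", function() {
  ts <- integrate_system(
    builtin_system("sinusoid", list(amplitude = 1, period = 30)), NULL,
    simulation_config(duration = 1500, dt_out = 2, transient = 30))
  ts_variable(ts, "x")
})

# Chaotic logistic map, r = 4: 5001 iterates after a 100-step transient.
logistic_x <- function() cached("logistic_x", function() {
  ts <- integrate_system(
    builtin_system("logistic_map", list(r = 4)), 0.1,
    simulation_config(duration = 5000, dt_out = 1, transient = 100))
  ts_variable(ts)
})

# Weakly damped linear oscillator (analytic dominant exponent -gamma/2).
damped_linear <- function(gamma = 0.05) {
  dynamical_system(
    "damped_linear", c("x", "v"),
    function(state, t, parameters) {
      c(state[2], -state[1] - parameters$gamma * state[2])
    },
    parameters = list(gamma = gamma), default_state = c(1, 0))
}

# Uniformly sampled sinusoidal time_series (for spectral tests).
sine_ts <- function(period, dt = 0.25, t_end = 1200, phase = 0) {
  t <- seq(0, t_end, by = dt)
  time_series(sin(2 * pi * t / period + phase), dt = dt)
}
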