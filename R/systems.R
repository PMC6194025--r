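#' Sinusoidal forcing specification
#'
#' Describes the nonnegative sinusoidal perturbation `a*sin(omega*t) + a`
#' that is superimposed on one state variable of a dynamical system. The
#' constant offset `a` keeps the perturbation nonnegative at all times, so
#' a forced concentration can never be driven below zero; `amplitude = 0`
#' recovers the autonomous (unforced) system. The angular frequency is
#' derived as `omega = 2*pi/period`.
#'
#' The amplitude is an additive *rate* amplitude, in units of
#' (concentration of the target variable) per (model time unit): the term
#' enters the time derivative of the target state. See the methods
#' vignette for the dimensional argument behind this convention.
#'
#' @param amplitude Forcing amplitude `a` (rate units), `>= 0`.
#' @param period Forcing period (time units), `> 0`.
#' @return An object of class `forcing_spec` with fields `amplitude`,
#'   `period` and the derived `omega`.
#' @seealso [forcing_term()], [make_forced_system()]
#' @examples
#' sp <- forcing_spec(amplitude = 1e-7, period = 30)
#' forcing_term(sp, c(7.5, 22.5))  # max 2e-7, min 0
#' @export
forcing_spec <- function(amplitude = 0, period = 30) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude) ||
      amplitude < 0) {
    stop("`amplitude` must be a single finite number >= 0", call. = FALSE)
  }
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0) {
    stop("`period` must be a single finite number > 0", call. = FALSE)
  }
  structure(
    list(amplitude = amplitude, period = period, omega = 2 * pi * (1 / period)),
    class = "forcing_spec"
  )
}

#' @export
print.forcing_spec <- function(x, ...) {
  cat(sprintf("<forcing_spec> a = %g, period = %g (omega = %g rad/time)\n",
              x$amplitude, x$period, x$omega))
  invisible(x)
}

#' Evaluate the sinusoidal forcing term
#'
#' Computes `a*sin(2*pi*t/period) + a`, the rate contribution added to the
#' forced state variable. The value lies in `[0, 2a]` for all `t` and is
#' identically zero when `amplitude = 0`.
#'
#' @param spec A [forcing_spec()].
#' @param t Time(s) at which to evaluate; vectorized.
#' @return Numeric vector of forcing values, never negative.
#' @export
forcing_term <- function(spec, t) {
  if (!inherits(spec, "forcing_spec")) {
    stop("`spec` must be a forcing_spec object", call. = FALSE)
  }
  spec$amplitude * sin(spec$omega * t) + spec$amplitude
}

#' Define a dynamical system plug-in
#'
#' The plug-in contract through which any model -- including large
#' mechanistic ODE systems such as bi-compartmental mitochondrial
#' energy-redox models -- is handed to the pipeline. A system is a
#' derivative evaluator plus metadata; for discrete maps the evaluator
#' returns the *next state* rather than a derivative.
#'
#' The evaluator must be deterministic (identical `(state, t, parameters)`
#' give identical output) and return finite values on the declared domain.
#'
#' @param name Label for the system.
#' @param state_names Character vector of state variable names (with units
#'   where meaningful); defines the dimension.
#' @param derivs Function `(state, t, parameters)` returning a numeric
#'   vector of the same length as `state`: time derivatives for flows, the
#'   next state for maps.
#' @param parameters Named list of parameter values.
#' @param is_discrete `TRUE` for maps, `FALSE` (default) for flows.
#' @param default_state Optional default initial state.
#' @return An object of class `dynamical_system`.
#' @seealso [builtin_system()], [make_forced_system()], [integrate_system()]
#' @export
dynamical_system <- function(name, state_names, derivs, parameters = list(),
                             is_discrete = FALSE, default_state = NULL) {
  stopifnot(is.character(state_names), length(state_names) >= 1L,
            is.function(derivs), is.list(parameters))
  if (length(parameters) && (is.null(names(parameters)) || any(names(parameters) == ""))) {
    stop("`parameters` must be a fully named list", call. = FALSE)
  }
  if (!is.null(default_state)) {
    default_state <- as.numeric(default_state)
    if (length(default_state) != length(state_names)) {
      stop("`default_state` length must equal the number of state variables",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, state_names = state_names, dimension = length(state_names),
         derivs = derivs, parameters = parameters,
         is_discrete = isTRUE(is_discrete), default_state = default_state),
    class = "dynamical_system"
  )
}

#' @export
print.dynamical_system <- function(x, ...) {
  cat(sprintf("<dynamical_system> %s (%s, dimension %d)\n", x$name,
              if (x$is_discrete) "discrete map" else "continuous flow",
              x$dimension))
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  if (length(x$parameters)) {
    cat("  parameters:",
        paste(sprintf("%s = %g", names(x$parameters),
                      unlist(x$parameters)), collapse = ", "), "\n")
  }
  invisible(x)
}

# Evaluate a system's derivative (or map update), with basic sanity checks.
eval_derivs <- function(system, state, t) {
  d <- system$derivs(state, t, system$parameters)
  if (length(d) != system$dimension) {
    stop(sprintf("derivative evaluator of '%s' returned %d values, expected %d",
                 system$name, length(d), system$dimension), call. = FALSE)
  }
  as.numeric(d)
}

#' Superimpose sinusoidal forcing on one state variable
#'
#' Returns a new system whose derivative for `target_variable` equals the
#' base system's derivative plus [forcing_term()]; all other derivatives
#' are unchanged. With `amplitude = 0` the forced system is identical to
#' the base system (autonomy recovery).
#'
#' @param base A [dynamical_system()].
#' @param spec A [forcing_spec()].
#' @param target_variable Name of the state variable receiving the forcing.
#' @return A forced `dynamical_system`.
#' @export
make_forced_system <- function(base, spec, target_variable) {
  stopifnot(inherits(base, "dynamical_system"), inherits(spec, "forcing_spec"))
  idx <- match(target_variable, base$state_names)
  if (is.na(idx)) {
    stop(sprintf("unknown state variable '%s'; valid names: %s",
                 target_variable, paste(base$state_names, collapse = ", ")),
         call. = FALSE)
  }
  base_derivs <- base$derivs
  forced_derivs <- function(state, t, parameters) {
    d <- base_derivs(state, t, parameters)
    d[idx] <- d[idx] + spec$amplitude * sin(spec$omega * t) + spec$amplitude
    d
  }
  out <- base
  out$name <- sprintf("%s + forcing(a=%g, T=%g) on %s", base$name,
                      spec$amplitude, spec$period, target_variable)
  out$derivs <- forced_derivs
  out$forcing <- spec
  out$forcing_target <- target_variable
  out
}

builtin_catalogue <- c("forced_brusselator", "rossler", "logistic_map",
                       "sinusoid", "quasiperiodic_two_tone")

#' Built-in benchmark systems
#'
#' A catalogue of fully specified systems spanning the dynamical regimes
#' the pipeline must handle: stable fixed points, limit cycles,
#' period-doubling cascades into chaos, entrainment to a forcing period,
#' and quasiperiodic multi-frequency signals.
#'
#' * `forced_brusselator` -- the designated redox surrogate: a two-variable
#'   chemical limit-cycle oscillator `dx/dt = A - (B+1)x + x^2 y + F(t)`,
#'   `dy/dt = Bx - x^2 y`, receiving the nonnegative sinusoidal forcing
#'   `F(t) = a*sin(2*pi*t/period) + a` on its first variable. Parameters:
#'   `A = 0.4`, `B = 1.2`, `amplitude = 0`, `period = 30`. Its forced
#'   regimes span entrainment, quasiperiodicity and chaos.
#' * `rossler` -- the Roessler flow (`a = 0.2, b = 0.2, c = 5.7`), a
#'   standard chaotic benchmark with known dominant Lyapunov exponent.
#' * `logistic_map` -- `x <- r x (1 - x)` (default growth rate 4), a
#'   discrete map with an analytic Lyapunov oracle.
#' * `sinusoid` -- harmonic oscillator emitting `amplitude*sin(2*pi*t/period)`
#'   in its first variable; a pure limit-cycle (zero-exponent) reference.
#' * `quasiperiodic_two_tone` -- sum of two incommensurate sinusoids
#'   (`periods = c(30, 30*sqrt(2))`, `amplitudes = c(1, 1)`); the first
#'   state `signal` carries the two-tone sum.
#'
#' @param name One of `"forced_brusselator"`, `"rossler"`, `"logistic_map"`,
#'   `"sinusoid"`, `"quasiperiodic_two_tone"`.
#' @param parameters Named list of parameter overrides (unknown names are
#'   an error).
#' @return A [dynamical_system()] with a sensible `default_state`.
#' @examples
#' sys <- builtin_system("logistic_map", list(r = 3.2))
#' @export
builtin_system <- function(name, parameters = list()) {
  if (!is.character(name) || length(name) != 1L || !(name %in% builtin_catalogue)) {
    stop(sprintf("unknown system '%s'; available systems: %s",
                 as.character(name)[1],
                 paste(builtin_catalogue, collapse = ", ")), call. = FALSE)
  }
  stopifnot(is.list(parameters))
  merge_params <- function(defaults) {
    bad <- setdiff(names(parameters), names(defaults))
    if (length(bad)) {
      stop(sprintf("unknown parameter(s) for '%s': %s (valid: %s)", name,
                   paste(bad, collapse = ", "),
                   paste(names(defaults), collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(defaults, parameters)
  }

  switch(name,
    forced_brusselator = {
      p <- merge_params(list(A = 0.4, B = 1.2, amplitude = 0, period = 30))
      base <- dynamical_system(
        name = "brusselator",
        state_names = c("x", "y"),
        derivs = function(state, t, parameters) {
          x <- state[1]; y <- state[2]
          c(parameters$A - (parameters$B + 1) * x + x * x * y,
            parameters$B * x - x * x * y)
        },
        parameters = p[c("A", "B")],
        default_state = c(p$A, p$B / p$A + 0.1)
      )
      if (p$amplitude > 0) {
        make_forced_system(base, forcing_spec(p$amplitude, p$period), "x")
      } else {
        base$name <- "forced_brusselator (a = 0)"
        base
      }
    },
    rossler = {
      p <- merge_params(list(a = 0.2, b = 0.2, c = 5.7))
      dynamical_system(
        name = "rossler",
        state_names = c("x", "y", "z"),
        derivs = function(state, t, parameters) {
          c(-state[2] - state[3],
            state[1] + parameters$a * state[2],
            parameters$b + state[3] * (state[1] - parameters$c))
        },
        parameters = p,
        default_state = c(1, 1, 1)
      )
    },
    logistic_map = {
      p <- merge_params(list(r = 4))
      dynamical_system(
        name = "logistic_map",
        state_names = "x",
        derivs = function(state, t, parameters) {
          parameters$r * state[1] * (1 - state[1])
        },
        parameters = p,
        is_discrete = TRUE,
        default_state = 0.1
      )
    },
    sinusoid = {
      p <- merge_params(list(amplitude = 1, period = 30))
      omega <- 2 * pi / p$period
      dynamical_system(
        name = "sinusoid",
        state_names = c("x", "v"),
        derivs = function(state, t, parameters) {
          w <- 2 * pi / parameters$period
          c(w * state[2], -w * state[1])
        },
        parameters = p,
        default_state = c(0, p$amplitude)
      )
    },
    quasiperiodic_two_tone = {
      p <- merge_params(list(periods = c(30, 30 * sqrt(2)),
                             amplitudes = c(1, 1)))
      stopifnot(length(p$periods) == 2L, length(p$amplitudes) == 2L)
      dynamical_system(
        name = "quasiperiodic_two_tone",
        state_names = c("signal", "x1", "v1", "x2", "v2"),
        derivs = function(state, t, parameters) {
          w1 <- 2 * pi / parameters$periods[1]
          w2 <- 2 * pi / parameters$periods[2]
          c(w1 * state[3] + w2 * state[5],
            w1 * state[3], -w1 * state[2],
            w2 * state[5], -w2 * state[4])
        },
        parameters = p,
        default_state = c(0, 0, p$amplitudes[1], 0, p$amplitudes[2])
      )
    }
  )
}

#' Mitochondrial energy-redox parameter seat
#'
#' Parameter container for the (externally supplied) bi-compartmental
#' mitochondrial energy-redox ODE model that this package was designed to
#' analyze. The model equations themselves are not shipped -- they plug in
#' through [dynamical_system()] -- but the named parameter slots document
#' the contract: SOD1 and SOD2 are the extra-mitochondrial Cu,Zn- and
#' matrix Mn-superoxide-dismutase concentrations (mM), `shunt` is the
#' fraction of respiratory-chain electrons diverted to superoxide, and
#' `adp_m` is the matrix ADP concentration (default 0.01 mM, energized
#' state-4 respiration). Flux entries for superoxide transport
#' (`V_Tr_ROS`), Cu,Zn-SOD scavenging (`V_CuZnSOD`) and the
#' matrix/extra-matrix volume ratio (`v_ratio`) are carried as named
#' members of the plug-in's parameter table; their functional forms belong
#' to the client model.
#'
#' @param sod2_conc Matrix Mn-SOD concentration (mM), `>= 0`.
#' @param sod1_conc Extra-mitochondrial Cu,Zn-SOD concentration (mM), `>= 0`.
#' @param shunt Electron shunt fraction in `[0, 1]`.
#' @param adp_m Matrix ADP concentration (mM), `>= 0`.
#' @param fluxes Optional named list of flux-table entries passed through
#'   to the client model.
#' @return A named list of class `mer_parameters`.
#' @export
mer_parameters <- function(sod2_conc, sod1_conc = 9.7e-5, shunt = 0.04,
                           adp_m = 0.01, fluxes = list()) {
  stopifnot(is.numeric(sod2_conc), sod2_conc >= 0,
            is.numeric(sod1_conc), sod1_conc >= 0,
            is.numeric(adp_m), adp_m >= 0)
  if (!is.numeric(shunt) || shunt < 0 || shunt > 1) {
    stop("`shunt` must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(
    c(list(sod2_conc = sod2_conc, sod1_conc = sod1_conc, shunt = shunt,
           adp_m = adp_m), fluxes),
    class = "mer_parameters"
  )
}
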