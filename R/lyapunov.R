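#' Dominant Lyapunov exponent by the Wolf orbital-divergence method
#'
#' Follows the fiducial trajectory through a delay embedding, co-evolves a
#' nearby neighbor for `evolve_steps` samples at a time, accumulates the
#' log separation ratios, and replaces the neighbor -- preferring a small
#' orientation change -- whenever the separation leaves the admissible
#' range. The estimate is the long-time average of the local divergence
#' rates divided by the total travel time along the orbit:
#' `lambda = sum(ln(d1/d0)) / total time`, reported per time unit of the
#' source series for flows and per iteration for maps.
#'
#' @param embedding A delay embedding from [delay_embed()] (at least
#'   `10 * evolve_steps` rows).
#' @param dt Sampling interval; defaults to the embedding's `dt`.
#' @param evolve_steps Evolution time between accumulations, in samples
#'   (default 3).
#' @param min_sep,max_sep Admissible neighbor separation; defaults 0.1% and
#'   10% of the attractor extent (the largest coordinate range).
#' @param angle_max Maximum orientation change accepted at replacement, in
#'   radians (default 0.3).
#' @param theiler Temporal exclusion window in samples; defaults to
#'   `tau * m`.
#' @return An object of class `lyapunov_result` with `dominant_exponent`,
#'   `n_replacements`, a `trace` (running estimate vs time, whose final
#'   value equals the exponent) and a `settings` snapshot.
#' @seealso [benettin_exponent()] for an independent oracle,
#'   [classify_chaotic()]
#' @export
wolf_exponent <- function(embedding, dt = NULL, evolve_steps = 3,
                          min_sep = NULL, max_sep = NULL, angle_max = 0.3,
                          theiler = NULL) {
  stopifnot(inherits(embedding, "delay_embedding"))
  E <- embedding$vectors
  dt <- dt %||% embedding$dt
  if (nrow(E) < 10 * evolve_steps) {
    stop(sprintf("embedding has %d rows; need at least 10 * evolve_steps = %d",
                 nrow(E), 10 * evolve_steps), call. = FALSE)
  }
  extent <- max(apply(E, 2L, function(col) diff(range(col))))
  if (extent <= 0) stop("degenerate embedding: zero attractor extent", call. = FALSE)
  min_sep <- min_sep %||% (0.001 * extent)
  max_sep <- max_sep %||% (0.1 * extent)
  theiler <- theiler %||% (embedding$spec$tau * embedding$spec$m)
  res <- wolf_cpp(E, dt, as.integer(evolve_steps), min_sep, max_sep,
                  angle_max, as.integer(theiler))
  structure(
    list(dominant_exponent = res$exponent,
         n_replacements = res$n_replacements,
         trace = data.frame(time = res$trace_time,
                            estimate = res$trace_estimate),
         settings = list(dt = dt, evolve_steps = evolve_steps,
                         min_sep = min_sep, max_sep = max_sep,
                         angle_max = angle_max, theiler = theiler,
                         tau = embedding$spec$tau, m = embedding$spec$m)),
    class = "lyapunov_result"
  )
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("<lyapunov_result> dominant exponent = %.5g per time unit (%d renormalizations)\n",
              x$dominant_exponent, x$n_replacements))
  invisible(x)
}

#' Export a Lyapunov result to JSON (and the trace to CSV)
#'
#' @param result A `lyapunov_result`.
#' @param path Output JSON path; the running-estimate trace is written next
#'   to it as `<path>.trace.csv`.
#' @return Invisibly, the paths written.
#' @export
write_lyapunov_result <- function(result, path) {
  stopifnot(inherits(result, "lyapunov_result"))
  jsonlite::write_json(
    list(exponent = result$dominant_exponent,
         units = "per time unit of the source series",
         n_replacements = result$n_replacements,
         settings = result$settings),
    path, auto_unbox = TRUE, digits = NA)
  trace_path <- paste0(path, ".trace.csv")
  utils::write.csv(result$trace, trace_path, row.names = FALSE)
  invisible(c(json = path, trace = trace_path))
}

#' Benettin twin-trajectory Lyapunov exponent
#'
#' Independent oracle for the dominant exponent, computed on the system
#' itself rather than on a reconstructed attractor: a twin trajectory is
#' started `perturbation_size` away from the fiducial one, both are
#' integrated for `renorm_interval`, the separation growth is logged, and
#' the twin is renormalized back to `perturbation_size` along the current
#' separation direction. The exponent is the mean log growth per unit
#' time. For discrete maps `renorm_interval` counts iterations.
#'
#' @param system A [dynamical_system()].
#' @param initial_state Starting state; `NULL` uses the system default.
#' @param horizon Total averaging time (after the transient), much longer
#'   than `renorm_interval`.
#' @param renorm_interval Time between renormalizations.
#' @param perturbation_size Initial twin separation (default `1e-8`).
#' @param transient Time discarded before averaging starts.
#' @param rel_tol,abs_tol Integrator tolerances for flows.
#' @return The exponent (numeric scalar), per time unit for flows and per
#'   iteration for maps.
#' @export
benettin_exponent <- function(system, initial_state = NULL, horizon,
                              renorm_interval = 1, perturbation_size = 1e-8,
                              transient = 0, rel_tol = 1e-9, abs_tol = 1e-12) {
  stopifnot(inherits(system, "dynamical_system"),
            horizon > renorm_interval, perturbation_size > 0)
  state <- as.numeric(initial_state %||% system$default_state)
  if (length(state) != system$dimension) {
    stop("initial state length does not match system dimension", call. = FALSE)
  }
  if (system$is_discrete) {
    return(benettin_map(system, state, horizon, renorm_interval,
                        perturbation_size, transient))
  }
  dim <- system$dimension
  func2 <- function(t, y, parms) {
    list(c(eval_derivs(system, y[seq_len(dim)], t),
           eval_derivs(system, y[dim + seq_len(dim)], t)))
  }
  advance <- function(y, t0, t1) {
    out <- deSolve::ode(y = y, times = c(t0, t1), func = func2, parms = NULL,
                        method = "lsoda", rtol = rel_tol, atol = abs_tol,
                        maxsteps = 1e5)
    y1 <- as.numeric(out[nrow(out), -1L])
    if (nrow(out) < 2L || !all(is.finite(y1))) {
      stop(sprintf("trajectory blowup near t = %g", t0), call. = FALSE)
    }
    y1
  }
  t0 <- 0
  if (transient > 0) {
    one <- function(t, y, parms) list(eval_derivs(system, y, t))
    out <- deSolve::ode(y = state, times = seq(0, transient, length.out = 101),
                        func = one, parms = NULL, method = "lsoda",
                        rtol = rel_tol, atol = abs_tol, maxsteps = 1e5)
    state <- as.numeric(out[nrow(out), -1L])
    if (!all(is.finite(state))) stop("trajectory blowup during transient", call. = FALSE)
    t0 <- transient
  }
  pert <- c(perturbation_size, rep(0, dim - 1L))
  y <- c(state, state + pert)
  n_chunks <- floor(horizon / renorm_interval)
  acc <- 0
  for (k in seq_len(n_chunks)) {
    y <- advance(y, t0, t0 + renorm_interval)
    t0 <- t0 + renorm_interval
    delta <- y[dim + seq_len(dim)] - y[seq_len(dim)]
    d <- sqrt(sum(delta^2))
    if (d <= 0) stop("twin trajectories collapsed; increase perturbation_size",
                     call. = FALSE)
    acc <- acc + log(d / perturbation_size)
    y[dim + seq_len(dim)] <- y[seq_len(dim)] + delta * (perturbation_size / d)
  }
  acc / (n_chunks * renorm_interval)
}

benettin_map <- function(system, state, horizon, renorm_interval,
                         perturbation_size, transient) {
  steps_per <- max(1L, as.integer(round(renorm_interval)))
  n_trans <- as.integer(round(transient))
  n_chunks <- floor(horizon / steps_per)
  x1 <- state
  t_iter <- 0L
  for (k in seq_len(n_trans)) {
    x1 <- eval_derivs(system, x1, t_iter); t_iter <- t_iter + 1L
  }
  x2 <- x1 + c(perturbation_size, rep(0, system$dimension - 1L))
  acc <- 0
  for (k in seq_len(n_chunks)) {
    for (s in seq_len(steps_per)) {
      x1 <- eval_derivs(system, x1, t_iter)
      x2 <- eval_derivs(system, x2, t_iter)
      t_iter <- t_iter + 1L
    }
    if (!all(is.finite(c(x1, x2)))) {
      stop(sprintf("trajectory blowup at iteration %d", t_iter), call. = FALSE)
    }
    d <- sqrt(sum((x2 - x1)^2))
    if (d <= 0) stop("twin trajectories collapsed; increase perturbation_size",
                     call. = FALSE)
    acc <- acc + log(d / perturbation_size)
    x2 <- x1 + (x2 - x1) * (perturbation_size / d)
  }
  acc / (n_chunks * steps_per)
}

#' Classify a Lyapunov result as chaotic
#'
#' A system with at least one positive Lyapunov exponent is chaotic; in
#' practice the estimate is compared against a small positive zero-band
#' `epsilon_zero` so that limit cycles (exponent 0 up to estimator noise)
#' are not misclassified.
#'
#' @param result A `lyapunov_result` or a bare numeric exponent.
#' @param epsilon_zero Positive zero-band half-width (default 0.005, in the
#'   exponent's inverse time units).
#' @return `TRUE` iff the dominant exponent exceeds `epsilon_zero`.
#' @export
classify_chaotic <- function(result, epsilon_zero = 0.005) {
  stopifnot(epsilon_zero > 0)
  lam <- if (inherits(result, "lyapunov_result")) result$dominant_exponent else as.numeric(result)
  isTRUE(lam > epsilon_zero)
}
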