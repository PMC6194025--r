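#' Locate local extrema of one variable
#'
#' Finds local maxima and minima by sign change of the discrete derivative.
#' Flat segments (zero differences) inherit the preceding slope, so a
#' plateau top counts once. A constant series yields empty lists; the
#' fixed-point decision is the caller's.
#'
#' @param ts A [time_series()] (>= 3 samples).
#' @param variable Variable name or index (default: first).
#' @return A list with numeric vectors `maxima` and `minima`, raw extremum
#'   values in time order.
#' @export
extract_extrema <- function(ts, variable = NULL) {
  x <- if (inherits(ts, "time_series")) ts_variable(ts, variable) else as.numeric(ts)
  if (length(x) < 3L) stop("need at least 3 samples to locate extrema", call. = FALSE)
  s <- sign(diff(x))
  # carry the previous slope through flat segments
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  ds <- diff(s)
  imax <- which(ds < 0) + 1L
  imin <- which(ds > 0) + 1L
  list(maxima = x[imax], minima = x[imin])
}

#' Cluster extremum values into distinct levels
#'
#' Single-linkage clustering of a stream of extremum values: sorted values
#' are split wherever the gap exceeds `tol * scale`, and each cluster is
#' represented by its mean. This is the "how many distinct peak levels"
#' counting used to label period-k regimes on orbit diagrams.
#'
#' @param x Numeric vector of extremum values.
#' @param tol Relative tolerance (fraction of `scale`), default 0.5%.
#' @param scale Reference scale; defaults to `diff(range(x))`.
#' @return Sorted numeric vector of cluster means (empty input passes
#'   through).
#' @export
distinct_values <- function(x, tol = 0.005, scale = NULL) {
  stopifnot(tol > 0)
  x <- as.numeric(x)
  if (!length(x)) return(numeric(0))
  if (is.null(scale)) scale <- diff(range(x))
  if (!is.finite(scale) || scale <= 0) return(mean(x))
  xs <- sort(x)
  grp <- cumsum(c(1, diff(xs) > tol * scale))
  as.numeric(tapply(xs, grp, mean))
}

#' Label the dynamical regime of one parameter point
#'
#' For continuous flows: `fixed_point` when the steady-state flag is set,
#' when no extrema survive the transient, or when the peak-to-peak
#' amplitude is below `amplitude_floor`; otherwise `period_k` with `k` the
#' number of distinct maxima (a sinusoidal limit cycle is `period_1`:
#' one maximum and one minimum level), and `complex` beyond `k_max`
#' distinct maxima, where peak counting becomes unreliable.
#'
#' For discrete maps (`is_discrete = TRUE`), `maxima` is the set of
#' distinct orbit values and `k` is the detected cycle length; a map fixed
#' point is a period-1 orbit, so `period_1` is returned for `k = 1`.
#'
#' @param maxima,minima Distinct extremum levels (already clustered by
#'   [distinct_values()]).
#' @param steady_state Logical: did the trajectory satisfy the
#'   derivative-magnitude criterion (see [detect_steady_state()])?
#' @param amplitude_floor Absolute peak-to-peak floor below which a flow is
#'   a fixed point (callers typically pass 1e-6 of the dynamic range).
#' @param k_max Maximum countable period before labeling `complex`.
#' @param is_discrete Map (`TRUE`) or flow (`FALSE`).
#' @return A regime label: `"fixed_point"`, `"period_k"`, or `"complex"`.
#' @export
classify_regime <- function(maxima, minima, steady_state = FALSE,
                            amplitude_floor = 0, k_max = 32,
                            is_discrete = FALSE) {
  if (is_discrete) {
    k <- length(maxima)
    if (steady_state || k <= 1L) return("period_1")
    return(if (k <= k_max) sprintf("period_%d", k) else "complex")
  }
  if (steady_state) return("fixed_point")
  if (!length(maxima) && !length(minima)) return("fixed_point")
  p2p <- if (length(maxima) && length(minima)) {
    max(maxima) - min(minima)
  } else {
    diff(range(c(maxima, minima)))
  }
  if (p2p < amplitude_floor) return("fixed_point")
  k <- max(1L, length(maxima))
  if (k <= k_max) sprintf("period_%d", k) else "complex"
}

#' Orbit/bifurcation diagram over a parameter sweep
#'
#' Re-integrates the system at each grid value, takes the final half of the
#' post-transient window, extracts extrema (flows) or orbit values (maps),
#' clusters them into distinct levels and labels the regime. Grid points
#' are mutually independent: a failed integration is recorded as missing
#' (`regime = NA`) and never aborts the sweep, and results do not depend on
#' evaluation order.
#'
#' @param system_factory Function mapping a parameter value to a
#'   [dynamical_system()].
#' @param parameter_name Label of the swept parameter.
#' @param grid Sorted, nonempty numeric vector of parameter values.
#' @param observed_variable Variable whose extrema are plotted.
#' @param config A [simulation_config()] applied at every grid point.
#' @param initial_state Initial state (vector, or function of the parameter
#'   value); `NULL` uses each system's default.
#' @param distinct_tol Relative clustering tolerance for
#'   [distinct_values()] (default 0.5% of the signal range).
#' @param k_max Maximum countable period (default 32).
#' @param amplitude_floor Peak-to-peak fraction of the sweep-wide dynamic
#'   range below which a flow is a fixed point (default 1e-6).
#' @return An object of class `bifurcation_diagram` with per-grid-value
#'   `maxima_sets`, `minima_sets` and `regime_labels`.
#' @export
bifurcation_sweep <- function(system_factory, parameter_name, grid,
                              observed_variable, config,
                              initial_state = NULL, distinct_tol = 0.005,
                              k_max = 32, amplitude_floor = 1e-6) {
  stopifnot(is.function(system_factory), length(grid) >= 1L,
            !is.unsorted(grid))
  init_for <- function(v) {
    if (is.function(initial_state)) initial_state(v) else initial_state
  }
  raw <- lapply(grid, function(v) {
    tryCatch({
      sys <- system_factory(v)
      ts <- integrate_system(sys, init_for(v), config)
      n <- nrow(ts$values)
      keep <- seq.int(ceiling(n / 2), n)  # final 50% of the window
      x <- ts_variable(ts, observed_variable)[keep]
      t_end <- ts$t_start + (n - 1L) * ts$dt
      ss <- detect_steady_state(sys, ts$values[n, ],
                                config$steady_state_epsilon, t = t_end)
      list(x = x, ss = ss, is_discrete = sys$is_discrete, error = NULL)
    }, error = function(e) list(x = NULL, ss = NA, is_discrete = NA,
                                error = conditionMessage(e)))
  })
  ranges <- vapply(raw, function(r) {
    if (is.null(r$x)) c(NA_real_, NA_real_) else range(r$x)
  }, numeric(2))
  dyn_range <- if (all(is.na(ranges))) 0 else {
    max(ranges[2, ], na.rm = TRUE) - min(ranges[1, ], na.rm = TRUE)
  }
  floor_abs <- amplitude_floor * dyn_range

  maxima_sets <- vector("list", length(grid))
  minima_sets <- vector("list", length(grid))
  regimes <- character(length(grid))
  errors <- character(length(grid))
  for (i in seq_along(grid)) {
    r <- raw[[i]]
    if (!is.null(r$error)) {
      maxima_sets[[i]] <- numeric(0); minima_sets[[i]] <- numeric(0)
      regimes[i] <- NA_character_; errors[i] <- r$error
      next
    }
    scale <- diff(range(r$x))
    if (isTRUE(r$is_discrete)) {
      vals <- distinct_values(r$x, distinct_tol, scale)
      maxima_sets[[i]] <- vals
      minima_sets[[i]] <- vals
      regimes[i] <- classify_regime(vals, vals, r$ss, floor_abs, k_max,
                                    is_discrete = TRUE)
    } else {
      ex <- extract_extrema(time_series(r$x, dt = config$dt_out))
      mx <- distinct_values(ex$maxima, distinct_tol, scale)
      mn <- distinct_values(ex$minima, distinct_tol, scale)
      regimes[i] <- classify_regime(mx, mn, r$ss, floor_abs, k_max)
      if (regimes[i] == "fixed_point") {
        # a fixed-point branch is one degenerate value per set
        v <- mean(r$x)
        mx <- v; mn <- v
      }
      maxima_sets[[i]] <- mx
      minima_sets[[i]] <- mn
    }
  }
  structure(
    list(parameter_name = parameter_name, parameter_values = grid,
         maxima_sets = maxima_sets, minima_sets = minima_sets,
         regime_labels = regimes, observed_variable = observed_variable,
         errors = errors),
    class = "bifurcation_diagram"
  )
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("<bifurcation_diagram> %s over %s in [%g, %g] (%d points)\n",
              x$observed_variable, x$parameter_name,
              min(x$parameter_values), max(x$parameter_values),
              length(x$parameter_values)))
  print(table(regime = x$regime_labels, useNA = "ifany"))
  invisible(x)
}

#' Long-format export of a bifurcation diagram
#'
#' One row per (parameter value, extremum), columns
#' `parameter_value, extremum_type, value, regime` -- the layout used for
#' red-maxima/blue-minima scatter plots.
#'
#' @param x A `bifurcation_diagram`.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.bifurcation_diagram <- function(x, ...) {
  rows <- lapply(seq_along(x$parameter_values), function(i) {
    mx <- x$maxima_sets[[i]]; mn <- x$minima_sets[[i]]
    if (!length(mx) && !length(mn)) return(NULL)
    data.frame(parameter_value = x$parameter_values[i],
               extremum_type = c(rep("max", length(mx)), rep("min", length(mn))),
               value = c(mx, mn),
               regime = x$regime_labels[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parameter_value = numeric(0),
                      extremum_type = character(0), value = numeric(0),
                      regime = character(0))
  }
  names(out)[1] <- "parameter_value"
  out
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  df <- as.data.frame(x)
  if (!nrow(df)) stop("empty diagram", call. = FALSE)
  graphics::plot(df$parameter_value, df$value, type = "n",
                 xlab = x$parameter_name, ylab = x$observed_variable, ...)
  is_max <- df$extremum_type == "max"
  graphics::points(df$parameter_value[is_max], df$value[is_max],
                   pch = 20, cex = 0.4, col = "red")
  graphics::points(df$parameter_value[!is_max], df$value[!is_max],
                   pch = 20, cex = 0.4, col = "blue")
  invisible(x)
}
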