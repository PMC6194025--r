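#' Uniformly sampled multivariate time series
#'
#' The central data container of the pipeline: an `n_samples x n_variables`
#' matrix sampled at a single, strictly uniform interval `dt` starting at
#' `t_start`. All downstream operations (extrema extraction, delay
#' embedding, periodograms) require uniform sampling; irregular
#' trajectories must first go through [resample_uniform()].
#'
#' @param values Numeric matrix (or vector for a single variable),
#'   `n_samples >= 2`, all values finite.
#' @param dt Sampling interval (time units), `> 0`.
#' @param t_start Time of the first sample.
#' @param variable_names Optional variable labels; defaults to column names
#'   or `V1, V2, ...`.
#' @return An object of class `time_series`.
#' @export
time_series <- function(values, dt, t_start = 0, variable_names = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("a time series needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values))) stop("time series values must all be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single finite number > 0", call. = FALSE)
  }
  if (is.null(variable_names)) {
    variable_names <- colnames(values) %||% paste0("V", seq_len(ncol(values)))
  }
  stopifnot(length(variable_names) == ncol(values))
  colnames(values) <- variable_names
  structure(
    list(values = values, dt = dt, t_start = t_start,
         variable_names = variable_names),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples x %d variable(s), dt = %g, t in [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$dt, x$t_start,
              x$t_start + (nrow(x$values) - 1L) * x$dt))
  cat("  variables:", paste(x$variable_names, collapse = ", "), "\n")
  invisible(x)
}

#' Sample times of a time series
#' @param ts A [time_series()].
#' @return Numeric vector of sample times.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$t_start + ts$dt * (seq_len(nrow(ts$values)) - 1L)
}

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time = ts_times(x), x$values, check.names = FALSE)
}

#' Extract one variable of a time series as a numeric vector
#'
#' @param ts A [time_series()].
#' @param variable Variable name or column index; `NULL` picks the first.
#' @return Numeric vector of samples.
#' @export
ts_variable <- function(ts, variable = NULL) {
  stopifnot(inherits(ts, "time_series"))
  if (is.null(variable)) return(ts$values[, 1L])
  if (is.character(variable)) {
    idx <- match(variable, ts$variable_names)
    if (is.na(idx)) {
      stop(sprintf("unknown variable '%s'; available: %s", variable,
                   paste(ts$variable_names, collapse = ", ")), call. = FALSE)
    }
    return(ts$values[, idx])
  }
  ts$values[, variable]
}

#' Write a time series to CSV with a JSON metadata sidecar
#'
#' The CSV has a header row `time,<var1>,<var2>,...`; full double precision
#' is preserved. A sidecar `<path>.json` records `dt`, `t_start`, variable
#' names and any attached simulation settings, making the file pair the
#' interchange format of the pipeline (and the ingestion path for
#' externally deposited series).
#'
#' @param ts A [time_series()].
#' @param path Output CSV path.
#' @return Invisibly, a character vector with the CSV and JSON paths.
#' @export
write_time_series <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  df <- as.data.frame(ts)
  header <- paste(c("time", ts$variable_names), collapse = ",")
  body <- do.call(paste, c(lapply(df, function(col) sprintf("%.17g", col)),
                           sep = ","))
  writeLines(c(header, body), path)
  meta <- list(dt = ts$dt, t_start = ts$t_start,
               variable_names = ts$variable_names,
               n_samples = nrow(ts$values))
  if (!is.null(attr(ts, "config"))) meta$config <- attr(ts, "config")
  json_path <- paste0(path, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = json_path))
}

#' Read a time series written by [write_time_series()]
#'
#' Accepts any delimited text file with a `time` column followed by one
#' column per variable; sampling must be uniform (checked against the time
#' column). If the JSON sidecar is present its metadata is used.
#'
#' @param path CSV path.
#' @param tol Relative tolerance on sampling uniformity.
#' @return A [time_series()].
#' @export
read_time_series <- function(path, tol = 1e-8) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("expected a 'time' column", call. = FALSE)
  tvec <- df$time
  vals <- as.matrix(df[setdiff(names(df), "time")])
  dts <- diff(tvec)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > tol * dt)) {
    stop("sampling is not uniform; use resample_uniform() first", call. = FALSE)
  }
  json_path <- paste0(path, ".json")
  if (file.exists(json_path)) {
    meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    dt <- meta$dt %||% dt
  }
  time_series(vals, dt = dt, t_start = tvec[1])
}

#' Resample an irregular trajectory onto a uniform grid
#'
#' Interpolates each variable with a cubic spline (dense-output analogue)
#' onto the grid `t[1] + k*dt_out`, `k = 0, ..., floor(span/dt_out)`. All
#' grid points lie within the original time span.
#'
#' @param t Numeric vector of (strictly increasing) sample times.
#' @param values Matrix or vector of samples, one row per time.
#' @param dt_out Output sampling interval; must not exceed the time span.
#' @return A [time_series()].
#' @export
resample_uniform <- function(t, values, dt_out) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  stopifnot(length(t) == nrow(values), length(t) >= 2L)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  span <- t[length(t)] - t[1]
  if (dt_out > span) {
    stop(sprintf("dt_out (%g) exceeds the trajectory time span (%g)",
                 dt_out, span), call. = FALSE)
  }
  grid <- t[1] + dt_out * (0:floor(span / dt_out))
  out <- apply(values, 2L, function(col) {
    stats::splinefun(t, col, method = "fmm")(grid)
  })
  time_series(out, dt = dt_out, t_start = grid[1],
              variable_names = colnames(values))
}
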