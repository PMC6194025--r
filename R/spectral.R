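#' One-sided FFT periodogram
#'
#' Computes the power spectrum of one variable on the frequency grid
#' `0, 1/(N dt), ..., Nyquist`. Normalization is such that the total power
#' excluding the DC bin equals the population variance of the (detrended)
#' series -- the Parseval identity the tests verify on every periodogram.
#' No taper is applied by default; a Hann window is available for leakage
#' control (power is rescaled to preserve the variance normalization).
#'
#' @param ts A [time_series()] (uniform sampling is guaranteed by the
#'   container; irregular trajectories must go through
#'   [resample_uniform()] first), or a plain numeric vector with `dt`.
#' @param variable Variable name/index (default: first).
#' @param detrend Remove the mean before transforming (default `TRUE`).
#' @param window `"none"` (default) or `"hann"`.
#' @param dt Sampling interval when `ts` is a bare vector.
#' @return An object of class `periodogram` with `frequencies` (Hz when
#'   `dt` is in seconds), `power`, and the source `variable`.
#' @export
periodogram <- function(ts, variable = NULL, detrend = TRUE,
                        window = c("none", "hann"), dt = NULL) {
  window <- match.arg(window)
  if (inherits(ts, "time_series")) {
    dt <- ts$dt
    varname <- if (is.character(variable)) variable else
      ts$variable_names[if (is.null(variable)) 1L else variable]
    x <- ts_variable(ts, variable)
  } else {
    if (is.null(dt)) stop("`dt` is required for a bare numeric series", call. = FALSE)
    varname <- "x"
    x <- as.numeric(ts)
  }
  n <- length(x)
  if (n < 16L) stop("need at least 16 samples for a periodogram", call. = FALSE)
  if (detrend) x <- x - mean(x)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
    x <- x * w / sqrt(mean(w^2))  # preserve total power
  }
  X <- stats::fft(x)
  p_full <- Mod(X)^2 / n^2
  half <- floor(n / 2) + 1L
  p <- p_full[seq_len(half)]
  if (n %% 2 == 0) {
    if (half > 2L) p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  } else {
    p[2:half] <- 2 * p[2:half]
  }
  structure(
    list(frequencies = (seq_len(half) - 1L) / (n * dt), power = p,
         variable = varname, n = n, dt = dt),
    class = "periodogram"
  )
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram> %s: %d bins, df = %g, Nyquist = %g\n",
              x$variable, length(x$power), x$frequencies[2],
              max(x$frequencies)))
  invisible(x)
}

#' @export
as.data.frame.periodogram <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, power = x$power)
}

#' Top-k dominant spectral peaks
#'
#' Local maxima of the power spectrum (DC excluded), filtered by a
#' prominence floor and returned in decreasing order of power. An empty
#' vector -- not an error -- signals that no peak clears the floor.
#'
#' @param pg A [periodogram()].
#' @param k Number of peaks requested (default 1).
#' @param min_prominence Power floor; default 10x the median non-DC power.
#' @return Numeric vector of up to `k` peak frequencies, rank-ordered.
#' @export
dominant_frequencies <- function(pg, k = 1, min_prominence = NULL) {
  stopifnot(inherits(pg, "periodogram"), k >= 1)
  p <- pg$power
  n <- length(p)
  min_prominence <- min_prominence %||% (10 * stats::median(p[-1L]))
  idx <- which(vapply(2:(n - 1L), function(i) {
    p[i] > p[i - 1L] && p[i] >= p[i + 1L] && p[i] >= min_prominence
  }, logical(1))) + 1L
  # the last bin can be a peak against its single neighbor
  if (n >= 2L && p[n] > p[n - 1L] && p[n] >= min_prominence) idx <- c(idx, n)
  if (!length(idx)) return(numeric(0))
  idx <- idx[order(p[idx], decreasing = TRUE)]
  pg$frequencies[utils::head(idx, k)]
}

#' Pairwise periodogram correlation matrix
#'
#' Pearson correlation between the power spectra of every pair of
#' variables. A high correlation means the variables share their principal
#' oscillatory frequencies; a value near 0 means their periodograms carry
#' completely different principal frequencies. Correlation is computed on
#' raw power by default; `log_power = TRUE` compresses dynamic range.
#'
#' @param x A multivariate [time_series()], or a list of single-variable
#'   `time_series` with identical `dt` and length.
#' @param detrend Passed to [periodogram()].
#' @param log_power Correlate `log10(power + eps)` instead of raw power.
#' @return An object of class `sync_matrix`: symmetric matrix with unit
#'   diagonal, entries in `[-1, 1]`; a zero-variance periodogram yields
#'   flagged `NA` entries (recorded in `$flagged`), never a silent 0.
#' @export
periodogram_correlation_matrix <- function(x, detrend = TRUE,
                                           log_power = FALSE) {
  if (inherits(x, "time_series")) {
    series <- lapply(seq_along(x$variable_names), function(i) {
      time_series(x$values[, i], dt = x$dt, t_start = x$t_start,
                  variable_names = x$variable_names[i])
    })
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "time_series"))) {
    series <- x
  } else {
    stop("`x` must be a time_series or a list of time_series", call. = FALSE)
  }
  dts <- vapply(series, function(s) s$dt, numeric(1))
  ns <- vapply(series, function(s) nrow(s$values), numeric(1))
  if (length(unique(dts)) != 1L || length(unique(ns)) != 1L) {
    stop("all series must share the same dt and length", call. = FALSE)
  }
  names_ <- vapply(series, function(s) s$variable_names[1], character(1))
  powers <- lapply(series, function(s) periodogram(s, detrend = detrend)$power)
  if (log_power) powers <- lapply(powers, function(p) log10(p + 1e-300))
  P <- do.call(cbind, powers)
  zero_var <- apply(P, 2L, stats::sd) == 0
  C <- suppressWarnings(stats::cor(P))
  diag(C) <- 1
  flagged <- which(zero_var)
  if (length(flagged)) {
    C[flagged, ] <- NA_real_
    C[, flagged] <- NA_real_
    diag(C) <- ifelse(seq_len(ncol(C)) %in% flagged, NA_real_, 1)
    warning(sprintf("zero-variance periodogram for: %s; correlations flagged NA",
                    paste(names_[flagged], collapse = ", ")), call. = FALSE)
  }
  dimnames(C) <- list(names_, names_)
  structure(list(variable_names = names_, correlations = C,
                 flagged = names_[flagged]),
            class = "sync_matrix")
}

#' @export
print.sync_matrix <- function(x, ...) {
  cat(sprintf("<sync_matrix> %d variables\n", length(x$variable_names)))
  print(round(x$correlations, 3))
  invisible(x)
}

#' @export
as.matrix.sync_matrix <- function(x, ...) x$correlations

#' Write a sync matrix as square CSV
#'
#' @param x A `sync_matrix`.
#' @param path Output path; the header row and first column carry the
#'   variable names.
#' @return Invisibly, `path`.
#' @export
write_sync_matrix <- function(x, path) {
  stopifnot(inherits(x, "sync_matrix"))
  utils::write.csv(as.data.frame(x$correlations), path, row.names = TRUE)
  invisible(path)
}

#' Entrainment of a response to a forcing period
#'
#' A forced oscillator is entrained when the period of its oscillatory
#' response is an integer multiple of the forcing period. The response
#' period is taken from the dominant periodogram peak; the tolerance is
#' relative to the forcing period and is widened, when necessary, to the
#' period uncertainty implied by one FFT frequency bin. With no forcing
#' (`forcing_period` missing/`NA`, the autonomous case) entrainment is
#' undefined and `NA` is returned, never `TRUE`.
#'
#' @param response A [time_series()] or [periodogram()] of the response.
#' @param forcing_period Forcing period (same time units); `NA` for the
#'   autonomous case.
#' @param tol Relative tolerance on the integer ratio (default 2%).
#' @param min_prominence Passed to [dominant_frequencies()].
#' @return A list with `entrained` (`TRUE`/`FALSE`/`NA`), the integer
#'   `multiple` (or `NA`), the estimated `response_period`, and a `reason`
#'   string for non-entrained verdicts.
#' @export
is_entrained <- function(response, forcing_period, tol = 0.02,
                         min_prominence = NULL) {
  if (is.null(forcing_period) || is.na(forcing_period)) {
    return(list(entrained = NA, multiple = NA_integer_,
                response_period = NA_real_,
                reason = "autonomous (no forcing): entrainment undefined"))
  }
  stopifnot(forcing_period > 0, tol > 0)
  pg <- if (inherits(response, "periodogram")) response else
    periodogram(response)
  f <- dominant_frequencies(pg, k = 1, min_prominence = min_prominence)
  if (!length(f) || f[1] <= 0) {
    return(list(entrained = FALSE, multiple = NA_integer_,
                response_period = NA_real_,
                reason = "no dominant spectral peak"))
  }
  p_resp <- 1 / f[1]
  mult <- round(p_resp / forcing_period)
  df <- pg$frequencies[2]
  tol_period <- max(tol * forcing_period, p_resp^2 * df)  # >= one FFT bin
  ok <- mult >= 1 && abs(p_resp - mult * forcing_period) <= tol_period
  list(entrained = ok,
       multiple = if (ok) as.integer(mult) else NA_integer_,
       response_period = p_resp,
       reason = if (ok) "dominant period is an integer multiple of the forcing period"
                else "dominant period is not an integer multiple of the forcing period")
}
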