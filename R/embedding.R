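#' Average mutual information between a series and its lagged copy
#'
#' Histogram-based estimate (equal-width bins over the series range) of the
#' mutual information, in bits, between `x(t)` and `x(t + lag)` for
#' `lag = 0, ..., max_lag`. The value at lag 0 is the marginal entropy
#' estimate and is the maximal point of the curve. The first minimum of
#' this curve is the standard choice of delay for phase-space
#' reconstruction.
#'
#' @param x Numeric vector or single-variable [time_series()]; must not be
#'   constant, and `length(x) > 4 * max_lag`.
#' @param max_lag Largest lag, in samples.
#' @param n_bins Number of equal-width histogram bins (default 16).
#' @return An object of class `ami_curve` with fields `lags`, `ami`
#'   (bits), `n_bins`.
#' @seealso [first_minimum()], [delay_embed()]
#' @export
average_mutual_information <- function(x, max_lag, n_bins = 16) {
  if (inherits(x, "time_series")) x <- ts_variable(x)
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(max_lag >= 1, n_bins >= 2)
  if (n <= 4 * max_lag) {
    stop(sprintf("series too short: need > %d samples for max_lag = %d",
                 4 * max_lag, max_lag), call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("constant series has zero entropy; AMI is undefined", call. = FALSE)
  }
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  ami <- vapply(0:max_lag, function(lag) {
    a <- bin[seq_len(n - lag)]
    b <- bin[seq_len(n - lag) + lag]
    joint <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins)
    m <- length(a)
    pj <- joint / m
    pa <- tabulate(a, nbins = n_bins) / m
    pb <- tabulate(b, nbins = n_bins) / m
    nz <- pj > 0
    ij <- which(nz)
    ia <- (ij - 1L) %/% n_bins + 1L
    ib <- (ij - 1L) %% n_bins + 1L
    sum(pj[nz] * log2(pj[nz] / (pa[ia] * pb[ib])))
  }, numeric(1))
  structure(list(lags = 0:max_lag, ami = ami, n_bins = n_bins,
                 units = "bits"), class = "ami_curve")
}

#' @export
print.ami_curve <- function(x, ...) {
  cat(sprintf("<ami_curve> lags 0..%d, %d bins; AMI(0) = %.3f bits\n",
              max(x$lags), x$n_bins, x$ami[1]))
  invisible(x)
}

#' First minimum of an AMI curve
#'
#' Returns the smallest lag `l` with `ami[l] < ami[l-1]` and
#' `ami[l] <= ami[l+1]` (plateaus take the earliest lag). If the curve has
#' no local minimum, the fallback is the first lag where the AMI drops
#' below `1/e` of its lag-0 value, returned with attribute
#' `fallback = TRUE` and a warning; if it never drops that far either, an
#' error is raised.
#'
#' @param curve An `ami_curve` with at least 3 lags.
#' @return Integer lag (in samples).
#' @export
first_minimum <- function(curve) {
  stopifnot(inherits(curve, "ami_curve"))
  a <- curve$ami
  n <- length(a)
  if (n < 3L) stop("AMI curve needs at least 3 lags", call. = FALSE)
  for (i in 2:(n - 1L)) {
    if (a[i] < a[i - 1L] && a[i] <= a[i + 1L]) {
      return(curve$lags[i])
    }
  }
  thr <- a[1] / exp(1)
  j <- which(a < thr)[1]
  if (!is.na(j)) {
    warning("AMI curve has no local minimum; falling back to the first lag ",
            "below 1/e of the lag-0 value", call. = FALSE)
    return(structure(curve$lags[j], fallback = TRUE))
  }
  stop("AMI curve has no minimum and never drops below 1/e of its lag-0 ",
       "value; increase max_lag", call. = FALSE)
}

#' Delay-embedding specification
#'
#' @param tau Lag in samples, `>= 1`.
#' @param m Embedding dimension, `>= 1`.
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(tau, m) {
  stopifnot(is.numeric(tau), tau >= 1, tau == round(tau),
            is.numeric(m), m >= 1, m == round(m))
  structure(list(tau = as.integer(tau), m = as.integer(m)),
            class = "embedding_spec")
}

#' Fraction of false nearest neighbors per embedding dimension
#'
#' For each candidate dimension `m`, finds every point's nearest neighbor
#' in the m-dimensional delay embedding (excluding temporally adjacent
#' points within the Theiler window) and flags the pair as "false" when
#' its separation grows disproportionately on extension to `m + 1`:
#' either the extra-coordinate growth exceeds `r_tol` times the m-dim
#' distance, or the extended distance exceeds `a_tol` times the attractor
#' size (standard deviation of the series). The smallest `m` whose false
#' fraction drops below ~1% is the embedding dimension at which the
#' attractor unfolds.
#'
#' @param x Numeric vector or single-variable [time_series()].
#' @param tau Delay in samples.
#' @param m_max Largest dimension tested.
#' @param r_tol Relative-growth threshold (default 15).
#' @param a_tol Attractor-size threshold (default 2).
#' @param theiler Temporal exclusion window in samples (default `tau`).
#' @return A `data.frame` with columns `m` and `fnn_fraction`.
#' @export
false_nearest_neighbors <- function(x, tau, m_max, r_tol = 15, a_tol = 2,
                                    theiler = tau) {
  if (inherits(x, "time_series")) x <- ts_variable(x)
  x <- as.numeric(x)
  stopifnot(tau >= 1, m_max >= 1)
  n_min <- m_max * tau + max(10L, 2L * theiler + 2L)
  if (length(x) < n_min) {
    stop(sprintf("series too short for m_max = %d, tau = %d: need at least %d samples",
                 m_max, tau, n_min), call. = FALSE)
  }
  frac <- fnn_cpp(x, as.integer(tau), as.integer(m_max), r_tol, a_tol,
                  as.integer(theiler))
  data.frame(m = seq_len(m_max), fnn_fraction = frac)
}

#' Delay-coordinate embedding
#'
#' Builds the matrix of delay vectors
#' `y(t) = [x(t), x(t + tau), ..., x(t + (m-1) tau)]`: exactly
#' `N - (m-1)*tau` rows, with column `j` of row `i` equal to sample
#' `i + (j-1)*tau`. With `m = 1` the embedding is the original series.
#'
#' @param x Numeric vector or single-variable [time_series()].
#' @param spec An [embedding_spec()] (or `tau` when `m` is given).
#' @param m Embedding dimension when `spec` is a plain lag.
#' @param variable Variable to embed when `x` is multivariate.
#' @return An object of class `delay_embedding` with fields `vectors`
#'   (matrix), `spec`, and the source `dt`.
#' @export
delay_embed <- function(x, spec, m = NULL, variable = NULL) {
  dt <- 1
  if (inherits(x, "time_series")) {
    dt <- x$dt
    x <- ts_variable(x, variable)
  }
  x <- as.numeric(x)
  if (!inherits(spec, "embedding_spec")) {
    if (is.null(m)) stop("give an embedding_spec, or both tau and m", call. = FALSE)
    spec <- embedding_spec(spec, m)
  }
  n <- length(x)
  n_vec <- n - (spec$m - 1L) * spec$tau
  if (n_vec < 1L) {
    stop(sprintf("series of length %d too short for m = %d, tau = %d",
                 n, spec$m, spec$tau), call. = FALSE)
  }
  vec <- matrix(NA_real_, nrow = n_vec, ncol = spec$m)
  for (j in seq_len(spec$m)) {
    vec[, j] <- x[seq_len(n_vec) + (j - 1L) * spec$tau]
  }
  structure(list(vectors = vec, spec = spec, dt = dt),
            class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("<delay_embedding> %d vectors, m = %d, tau = %d samples (dt = %g)\n",
              nrow(x$vectors), x$spec$m, x$spec$tau, x$dt))
  invisible(x)
}

#' Choose lag and dimension automatically
#'
#' Convenience wrapper: lag from the first AMI minimum, dimension from the
#' first `m` whose FNN fraction drops below `fnn_threshold`.
#'
#' @param x Numeric vector or single-variable [time_series()].
#' @param max_lag Largest lag scanned for the AMI minimum (default
#'   `floor(length(x)/5)` capped at 200).
#' @param m_max Largest dimension tested (default 8).
#' @param n_bins AMI histogram bins.
#' @param fnn_threshold Acceptance threshold on the FNN fraction
#'   (default 0.01).
#' @param r_tol,a_tol,theiler Passed to [false_nearest_neighbors()].
#' @return An [embedding_spec()]; attributes `ami_curve` and `fnn` carry
#'   the diagnostics.
#' @export
select_embedding <- function(x, max_lag = NULL, m_max = 8, n_bins = 16,
                             fnn_threshold = 0.01, r_tol = 15, a_tol = 2,
                             theiler = NULL) {
  if (inherits(x, "time_series")) x <- ts_variable(x)
  x <- as.numeric(x)
  max_lag <- max_lag %||% min(200L, floor(length(x) / 5))
  curve <- average_mutual_information(x, max_lag = max_lag, n_bins = n_bins)
  tau <- as.integer(first_minimum(curve))
  fnn <- false_nearest_neighbors(x, tau = tau, m_max = m_max, r_tol = r_tol,
                                 a_tol = a_tol, theiler = theiler %||% tau)
  ok <- which(fnn$fnn_fraction < fnn_threshold)
  m <- if (length(ok)) ok[1] else m_max
  out <- embedding_spec(tau, m)
  attr(out, "ami_curve") <- curve
  attr(out, "fnn") <- fnn
  out
}
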