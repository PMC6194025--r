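#' Amplitude-by-period chaos map
#'
#' The end-to-end sweep: for every (amplitude, period) cell the base system
#' is forced on `target_variable`, integrated past the transient, the
#' observed variable is delay-embedded (per-cell AMI/FNN selection, or a
#' fixed [embedding_spec()]), the dominant Lyapunov exponent is estimated
#' by [wolf_exponent()], and the cell is classified:
#'
#' * `chaotic` -- exponent `> epsilon_zero`;
#' * `non_chaotic` -- exponent within/below the zero band (fixed points,
#'   limit cycles, entrained and quasiperiodic responses);
#' * `impaired` -- the trajectory collapsed to a near-zero-amplitude state
#'   (peak-to-peak below `impaired_floor` of the signal magnitude), the
#'   forced-to-death regime; no exponent is estimated;
#' * `failed` -- the cell errored (recorded, never aborts the sweep).
#'
#' Cells are mutually independent, so the map is deterministic given the
#' configuration and does not depend on evaluation order.
#'
#' @param base_system The autonomous [dynamical_system()].
#' @param target_variable State variable receiving the forcing.
#' @param amplitudes,periods Numeric grids (nonempty); `amplitude = 0`
#'   cells analyze the autonomous system.
#' @param config A [simulation_config()] used for every cell.
#' @param observed_variable Variable analyzed (default: the forced one).
#' @param embedding `NULL` for per-cell AMI/FNN selection, or a fixed
#'   [embedding_spec()].
#' @param epsilon_zero Zero band for [classify_chaotic()] (default 0.005).
#' @param impaired_floor Relative peak-to-peak floor for the `impaired`
#'   label (default 1e-6).
#' @param evolve_steps,angle_max,min_sep,max_sep,theiler Passed to
#'   [wolf_exponent()].
#' @param m_max,n_bins,max_lag Passed to [select_embedding()] when
#'   `embedding` is `NULL`.
#' @return An object of class `chaos_matrix`: `exponents` and `classes`
#'   matrices (amplitudes x periods) plus grids and settings.
#' @export
build_chaos_matrix <- function(base_system, target_variable, amplitudes,
                               periods, config,
                               observed_variable = target_variable,
                               embedding = NULL, epsilon_zero = 0.005,
                               impaired_floor = 1e-6, evolve_steps = 3,
                               angle_max = 0.3, min_sep = NULL,
                               max_sep = NULL, theiler = NULL, m_max = 6,
                               n_bins = 16, max_lag = NULL) {
  stopifnot(inherits(base_system, "dynamical_system"),
            length(amplitudes) >= 1L, length(periods) >= 1L,
            inherits(config, "simulation_config"))
  na <- length(amplitudes); np <- length(periods)
  exponents <- matrix(NA_real_, na, np,
                      dimnames = list(amplitude = amplitudes,
                                      period = periods))
  classes <- matrix(NA_character_, na, np, dimnames = dimnames(exponents))
  for (ia in seq_len(na)) {
    for (ip in seq_len(np)) {
      cell <- tryCatch({
        spec <- forcing_spec(amplitudes[ia], periods[ip])
        forced <- make_forced_system(base_system, spec, target_variable)
        ts <- integrate_system(forced, NULL, config)
        x <- ts_variable(ts, observed_variable)
        p2p <- diff(range(x))
        if (p2p < impaired_floor * max(max(abs(x)), .Machine$double.eps)) {
          list(exponent = NA_real_, class = "impaired")
        } else {
          espec <- embedding %||% select_embedding(
            x, max_lag = max_lag, m_max = m_max, n_bins = n_bins)
          emb <- delay_embed(x, espec)
          emb$dt <- ts$dt
          lam <- wolf_exponent(emb, evolve_steps = evolve_steps,
                               min_sep = min_sep, max_sep = max_sep,
                               angle_max = angle_max, theiler = theiler)
          list(exponent = lam$dominant_exponent,
               class = if (classify_chaotic(lam, epsilon_zero)) "chaotic"
                       else "non_chaotic")
        }
      }, error = function(e) list(exponent = NA_real_, class = "failed",
                                  message = conditionMessage(e)))
      exponents[ia, ip] <- cell$exponent
      classes[ia, ip] <- cell$class
    }
  }
  structure(
    list(amplitudes = amplitudes, periods = periods, exponents = exponents,
         classes = classes, epsilon_zero = epsilon_zero,
         settings = list(system = base_system$name,
                         target_variable = target_variable,
                         observed_variable = observed_variable,
                         impaired_floor = impaired_floor,
                         evolve_steps = evolve_steps, angle_max = angle_max,
                         duration = config$duration, dt_out = config$dt_out,
                         transient = config$transient, seed = config$seed)),
    class = "chaos_matrix"
  )
}

#' @export
print.chaos_matrix <- function(x, ...) {
  cat(sprintf("<chaos_matrix> %d amplitudes x %d periods (%s)\n",
              length(x$amplitudes), length(x$periods), x$settings$system))
  print(table(class = as.vector(x$classes)))
  invisible(x)
}

#' Long-format export of a chaos map
#'
#' @param x A `chaos_matrix`.
#' @param ... Unused.
#' @return A `data.frame` with one row per cell:
#'   `amplitude, period, exponent, class`.
#' @export
as.data.frame.chaos_matrix <- function(x, ...) {
  grid <- expand.grid(amplitude = x$amplitudes, period = x$periods,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(grid, exponent = as.vector(x$exponents),
             class = as.vector(x$classes))
}

#' Export a chaos map to CSV + JSON metadata
#'
#' The CSV is long-format (`amplitude, period, exponent, class`) with full
#' double precision, so a round-trip read reproduces the exponents
#' bit-exactly; the JSON carries grids, the zero band and all settings.
#'
#' @param matrix_ A `chaos_matrix`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
export_chaos_matrix <- function(matrix_, path) {
  stopifnot(inherits(matrix_, "chaos_matrix"))
  df <- as.data.frame(matrix_)
  header <- "amplitude,period,exponent,class"
  body <- sprintf("%.17g,%.17g,%s,%s", df$amplitude, df$period,
                  ifelse(is.na(df$exponent), "NA",
                         sprintf("%.17g", df$exponent)),
                  df$class)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(amplitudes = matrix_$amplitudes, periods = matrix_$periods,
         epsilon_zero = matrix_$epsilon_zero, settings = matrix_$settings),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = json_path))
}

#' @export
plot.chaos_matrix <- function(x, ...) {
  z <- matrix(as.integer(x$classes == "chaotic"), nrow = length(x$amplitudes))
  z[x$classes == "failed" | x$classes == "impaired"] <- NA
  graphics::image(x = seq_along(x$amplitudes), y = seq_along(x$periods),
                  z = z, col = c("darkgreen", "red3"), zlim = c(0, 1),
                  xlab = "forcing amplitude", ylab = "forcing period",
                  axes = FALSE, ...)
  graphics::axis(1, at = seq_along(x$amplitudes), labels = x$amplitudes)
  graphics::axis(2, at = seq_along(x$periods), labels = x$periods)
  graphics::box()
  invisible(x)
}
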