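#' Read a pipeline configuration file (YAML or JSON)
#'
#' Configuration files select a system and its parameter overrides, the
#' forcing grids, integration settings and algorithm settings, e.g.:
#'
#' ```yaml
#' system:
#'   name: forced_brusselator
#'   parameters: {A: 0.4, B: 1.5}
#' forcing:
#'   target_variable: x
#'   amplitudes: [0, 0.04, 0.08]
#'   periods: [6, 11]
#' simulation: {duration: 2000, transient: 400, dt_out: 0.25}
#' algorithm: {epsilon_zero: 0.005, n_bins: 16, m_max: 6}
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list (class `chaoscan_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$system$name)) {
    stop("config must define system$name", call. = FALSE)
  }
  structure(cfg, class = c("chaoscan_config", "list"))
}

#' Run a chaos-map sweep from a configuration
#'
#' Thin driver over [builtin_system()] (or a caller-supplied system),
#' [simulation_config()] and [build_chaos_matrix()]; optionally exports the
#' result with [export_chaos_matrix()].
#'
#' @param config A `chaoscan_config` (or path to one), see [read_config()].
#' @param out_dir Optional output directory for `chaos_map.csv` (+ JSON).
#' @param system Optional [dynamical_system()] overriding the config's
#'   builtin selection (the plug-in path for external models).
#' @return A `chaos_matrix`.
#' @export
run_chaos_map <- function(config, out_dir = NULL, system = NULL) {
  if (is.character(config)) config <- read_config(config)
  sysdef <- config$system %||% list()
  base <- system %||% builtin_system(sysdef$name,
                                     as.list(sysdef$parameters %||% list()))
  fr <- config$forcing %||% list()
  sim <- config$simulation %||% list()
  alg <- config$algorithm %||% list()
  cfg <- simulation_config(
    duration = sim$duration %||% 2000,
    dt_out = sim$dt_out %||% 0.25,
    transient = sim$transient %||% 400,
    rel_tol = sim$rel_tol %||% 1e-9,
    abs_tol = sim$abs_tol %||% 1e-12,
    steady_state_epsilon = sim$steady_state_epsilon %||% 1e-10,
    seed = sim$seed
  )
  emb <- if (!is.null(alg$tau) && !is.null(alg$m)) {
    embedding_spec(alg$tau, alg$m)
  }
  cm <- build_chaos_matrix(
    base_system = base,
    target_variable = fr$target_variable %||% base$state_names[1],
    amplitudes = as.numeric(fr$amplitudes %||% 0),
    periods = as.numeric(fr$periods %||% 30),
    config = cfg,
    observed_variable = fr$observed_variable %||% fr$target_variable %||%
      base$state_names[1],
    embedding = emb,
    epsilon_zero = alg$epsilon_zero %||% 0.005,
    evolve_steps = alg$evolve_steps %||% 3,
    m_max = alg$m_max %||% 6,
    n_bins = alg$n_bins %||% 16
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_chaos_matrix(cm, file.path(out_dir, "chaos_map.csv"))
  }
  cm
}
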