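test_that("a limit-cycle cell is classified non_chaotic with a near-zero exponent", {
  base <- builtin_system("forced_brusselator")  # B = 1.2: autonomous limit cycle
  cfg <- simulation_config(duration = 800, dt_out = 0.25, transient = 200)
  cm <- build_chaos_matrix(base, "x", amplitudes = 0, periods = 30,
                           config = cfg, m_max = 4)
  expect_s3_class(cm, "chaos_matrix")
  expect_equal(dim(cm$exponents), c(1L, 1L))
  expect_equal(cm$classes[1, 1], "non_chaotic")
  expect_lt(abs(cm$exponents[1, 1]), 0.005)
})

test_that("a fixed embedding_spec bypasses per-cell AMI/FNN selection", {
  base <- builtin_system("forced_brusselator")
  cfg <- simulation_config(duration = 600, dt_out = 0.25, transient = 150)
  cm <- build_chaos_matrix(base, "x", amplitudes = 0, periods = 30,
                           config = cfg, embedding = embedding_spec(15, 2))
  expect_equal(cm$classes[1, 1], "non_chaotic")
})

test_that("a trajectory pinned at a stable fixed point is labeled impaired", {
  # B = 0.5 < 1 + A^2: stable fixed point at (A, B/A); start exactly there
  base <- builtin_system("forced_brusselator", list(B = 0.5))
  base$default_state <- c(0.4, 0.5 / 0.4)
  cfg <- simulation_config(duration = 400, dt_out = 0.25, transient = 100)
  cm <- build_chaos_matrix(base, "x", amplitudes = 0, periods = 30,
                           config = cfg)
  expect_equal(cm$classes[1, 1], "impaired")
  expect_true(is.na(cm$exponents[1, 1]))
})

test_that("a diverging cell is recorded as failed without aborting the sweep", {
  explode <- dynamical_system("explode", "x",
                              function(state, t, parameters) state^2,
                              default_state = 1)
  cfg <- simulation_config(duration = 10, dt_out = 0.1)
  cm <- suppressWarnings(
    build_chaos_matrix(explode, "x", amplitudes = c(0, 0.1), periods = 5,
                       config = cfg))
  expect_true(all(cm$classes == "failed"))
  expect_true(all(is.na(cm$exponents)))
})

test_that("export round trip reproduces the exponents bit-exactly", {
  base <- builtin_system("forced_brusselator")
  cfg <- simulation_config(duration = 600, dt_out = 0.25, transient = 150)
  cm <- build_chaos_matrix(base, "x", amplitudes = 0, periods = 30,
                           config = cfg, embedding = embedding_spec(15, 2))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  export_chaos_matrix(cm, path)
  back <- utils::read.csv(path)
  expect_named(back, c("amplitude", "period", "exponent", "class"))
  expect_identical(back$exponent, as.vector(cm$exponents))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$epsilon_zero, cm$epsilon_zero)
  expect_equal(meta$settings$system, cm$settings$system)
})

test_that("run_chaos_map drives a sweep from a YAML config and exports it", {
  cfg_path <- tempfile(fileext = ".yaml")
  out_dir <- tempfile()
  on.exit(unlink(c(cfg_path, out_dir), recursive = TRUE), add = TRUE)
  writeLines(c(
    "system:",
    "  name: forced_brusselator",
    "  parameters: {A: 0.4, B: 1.2}",
    "forcing:",
    "  target_variable: x",
    "  amplitudes: [0]",
    "  periods: [30]",
    "simulation: {duration: 600, transient: 150, dt_out: 0.25}",
    "algorithm: {epsilon_zero: 0.005, tau: 15, m: 2}"), cfg_path)
  cm <- run_chaos_map(cfg_path, out_dir = out_dir)
  expect_s3_class(cm, "chaos_matrix")
  expect_equal(cm$classes[1, 1], "non_chaotic")
  expect_true(file.exists(file.path(out_dir, "chaos_map.csv")))
  expect_true(file.exists(file.path(out_dir, "chaos_map.csv.json")))
})

test_that("read_config accepts JSON too and validates the system name", {
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p), add = TRUE)
  jsonlite::write_json(list(system = list(name = "rossler")), p,
                       auto_unbox = TRUE)
  cfg <- read_config(p)
  expect_s3_class(cfg, "chaoscan_config")
  expect_equal(cfg$system$name, "rossler")
  p2 <- tempfile(fileext = ".json")
  on.exit(unlink(p2), add = TRUE)
  jsonlite::write_json(list(forcing = list(amplitudes = 1)), p2,
                       auto_unbox = TRUE)
  expect_error(read_config(p2), "system")
  expect_error(read_config("/nonexistent/config.yaml"), "not found")
})
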