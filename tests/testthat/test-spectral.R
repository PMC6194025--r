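test_that("periodogram satisfies the Parseval identity (even and odd N)", {
  set.seed(42)
  for (n in c(256, 257, 1000, 1001)) {
    x <- rnorm(n) + sin(2 * pi * seq_len(n) / 25)
    pg <- periodogram(x, dt = 0.5)
    xc <- x - mean(x)
    expect_equal(sum(pg$power[-1]), mean(xc^2), tolerance = 1e-10)
  }
})

test_that("frequency grid: DC first, spacing 1/(N dt), Nyquist last", {
  x <- rnorm(200)
  pg <- periodogram(x, dt = 0.25)
  expect_equal(pg$frequencies[1], 0)
  expect_equal(diff(pg$frequencies), rep(1 / (200 * 0.25), length(pg$power) - 1L))
  expect_equal(max(pg$frequencies), 0.5 / 0.25)
  expect_error(periodogram(rnorm(10), dt = 1), "16 samples")
  expect_error(periodogram(rnorm(100)), "dt")
})

test_that("a pure tone concentrates its power in the matching bin", {
  ts <- sine_ts(period = 30, dt = 0.25, t_end = 1200)
  pg <- periodogram(ts)
  f_hat <- dominant_frequencies(pg, k = 1)
  expect_equal(f_hat, 1 / 30, tolerance = pg$frequencies[2])
  # Hann window preserves the variance normalization
  pgh <- periodogram(ts, window = "hann")
  x <- ts_variable(ts); x <- x - mean(x)
  expect_equal(sum(pgh$power[-1]), mean(x^2), tolerance = 1e-2)
})

test_that("dominant_frequencies ranks peaks by power and can return none", {
  t <- seq(0, 2000, by = 0.5)
  two <- time_series(2 * sin(2 * pi * t / 40) + sin(2 * pi * t / 11), dt = 0.5)
  f2 <- dominant_frequencies(periodogram(two), k = 2)
  expect_length(f2, 2)
  expect_equal(f2[1], 1 / 40, tolerance = 1e-3)
  expect_equal(f2[2], 1 / 11, tolerance = 1e-3)
  # flat spectrum with a sky-high floor: no peak qualifies
  set.seed(9)
  pg <- periodogram(rnorm(512), dt = 1)
  expect_identical(dominant_frequencies(pg, min_prominence = 1e6), numeric(0))
})

test_that("is_entrained accepts integer period multiples within tolerance", {
  r1 <- is_entrained(sine_ts(30), 30)
  expect_true(r1$entrained)
  expect_equal(r1$multiple, 1L)
  r2 <- is_entrained(sine_ts(60), 30)
  expect_true(r2$entrained)
  expect_equal(r2$multiple, 2L)
  # irrational period ratio is rejected
  r3 <- is_entrained(sine_ts(30 * sqrt(2)), 30)
  expect_false(r3$entrained)
  expect_true(is.na(r3$multiple))
  # autonomous case: entrainment undefined, never TRUE
  r4 <- is_entrained(sine_ts(30), NA)
  expect_true(is.na(r4$entrained))
  expect_match(r4$reason, "autonomous")
})

test_that("sync matrix: identical spectra correlate at 1, disjoint tones near 0", {
  t <- seq(0, 1200, by = 0.25)
  same <- time_series(cbind(a = sin(2 * pi * t / 30),
                            b = sin(2 * pi * t / 30 + 1.2)), dt = 0.25)
  sm <- periodogram_correlation_matrix(same)
  expect_s3_class(sm, "sync_matrix")
  expect_equal(sm$correlations, matrix(1, 2, 2, dimnames = list(c("a", "b"),
                                                                c("a", "b"))),
               tolerance = 1e-6)
  mixed <- time_series(cbind(a = sin(2 * pi * t / 30),
                             c = sin(2 * pi * t / 7.3)), dt = 0.25)
  sm2 <- periodogram_correlation_matrix(mixed)
  expect_lt(abs(sm2$correlations["a", "c"]), 0.1)
  expect_equal(diag(sm2$correlations), c(a = 1, c = 1))
  expect_equal(sm2$correlations, t(sm2$correlations))
})

test_that("zero-variance series are flagged NA with a warning, never silent 0", {
  t <- seq(0, 300, by = 0.25)
  x <- time_series(cbind(a = sin(2 * pi * t / 30), flat = rep(2, length(t))),
                   dt = 0.25)
  expect_warning(sm <- periodogram_correlation_matrix(x), "flat")
  expect_true(is.na(sm$correlations["a", "flat"]))
  expect_equal(sm$flagged, "flat")
})

test_that("write_sync_matrix exports a labeled square CSV", {
  t <- seq(0, 300, by = 0.25)
  x <- time_series(cbind(a = sin(2 * pi * t / 30), b = cos(2 * pi * t / 30)),
                   dt = 0.25)
  sm <- periodogram_correlation_matrix(x)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_sync_matrix(sm, path)
  back <- utils::read.csv(path, row.names = 1)
  expect_equal(as.matrix(back), sm$correlations, tolerance = 1e-12,
               ignore_attr = TRUE)
})
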