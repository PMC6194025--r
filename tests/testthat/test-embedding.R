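test_that("AMI is maximal at lag 0 and near zero for independent noise", {
  set.seed(21)
  x <- runif(4000)
  curve <- average_mutual_information(x, max_lag = 20)
  expect_s3_class(curve, "ami_curve")
  expect_equal(curve$lags, 0:20)
  expect_equal(which.max(curve$ami), 1L)
  # iid samples share no information at positive lags (finite-sample bias
  # of the 16-bin histogram stays well below 0.2 bits at n = 4000)
  expect_true(all(curve$ami[-1] < 0.2))
  expect_true(curve$ami[1] > 3)  # ~log2(16) bits for a uniform marginal
})

test_that("AMI input validation", {
  expect_error(average_mutual_information(rep(1, 500), max_lag = 10),
               "constant")
  expect_error(average_mutual_information(rnorm(30), max_lag = 10),
               "too short")
})

test_that("first_minimum finds the earliest local minimum, with 1/e fallback", {
  mk <- function(vals) structure(list(lags = seq_along(vals) - 1L, ami = vals,
                                      n_bins = 16, units = "bits"),
                                 class = "ami_curve")
  expect_equal(first_minimum(mk(c(4, 2, 1, 2, 0.5, 2))), 2)
  # monotone decay: no local minimum -> first lag below 1/e of AMI(0)
  decay <- 4 * exp(-(0:10) / 2)
  expect_warning(got <- first_minimum(mk(decay)), "1/e")
  expect_equal(as.integer(got), 3L)  # 4*exp(-1.5) < 4/e
  expect_true(isTRUE(attr(got, "fallback")))
  # never dropping below 1/e is an error
  expect_error(suppressWarnings(first_minimum(mk(c(4, 3.9, 3.8, 3.7)))),
               "increase max_lag")
})

test_that("sinusoid AMI first minimum sits at the quarter period", {
  # dt = 2 for period 30 -> T/4 = 3.75 lags
  curve <- average_mutual_information(sinusoid_x(), max_lag = 30)
  tau <- first_minimum(curve)
  expect_true(abs(tau - 30 / 4 / 2) <= 1)
})

test_that("delay_embed produces exactly N - (m-1)*tau lagged vectors", {
  set.seed(33)
  for (rep in 1:5) {
    N <- sample(200:2000, 1)
    tau <- sample(1:20, 1)
    m <- sample(1:6, 1)
    x <- rnorm(N)
    emb <- delay_embed(x, embedding_spec(tau, m))
    expect_equal(nrow(emb$vectors), N - (m - 1) * tau)
    expect_equal(ncol(emb$vectors), m)
    # column j of row i is sample i + (j-1)*tau
    i <- sample(nrow(emb$vectors), 1)
    expect_equal(emb$vectors[i, ], x[i + (seq_len(m) - 1) * tau])
  }
  expect_error(delay_embed(rnorm(10), embedding_spec(5, 4)), "too short")
  expect_error(delay_embed(rnorm(10), 5), "embedding_spec")
})

test_that("delay_embed carries dt from a time_series source", {
  ts <- time_series(sin(1:100), dt = 0.3)
  emb <- delay_embed(ts, embedding_spec(2, 3))
  expect_equal(emb$dt, 0.3)
})

test_that("FNN unfolds the sinusoid at m = 2 and the Roessler attractor at m = 3", {
  fnn_s <- false_nearest_neighbors(sinusoid_x(), tau = 4, m_max = 3)
  expect_named(fnn_s, c("m", "fnn_fraction"))
  expect_lt(fnn_s$fnn_fraction[2], 0.01)
  fnn_r <- false_nearest_neighbors(rossler_x(), tau = 14, m_max = 4)
  expect_gt(fnn_r$fnn_fraction[2], 0.01)
  expect_lt(fnn_r$fnn_fraction[3], 0.01)
})

test_that("FNN of white noise does not unfold at low dimension", {
  set.seed(5)
  fnn <- false_nearest_neighbors(runif(3000), tau = 1, m_max = 3)
  expect_gt(fnn$fnn_fraction[2], 0.05)
})

test_that("select_embedding returns the AMI/FNN-selected spec with diagnostics", {
  spec <- select_embedding(rossler_x(), max_lag = 100, m_max = 6)
  expect_s3_class(spec, "embedding_spec")
  expect_true(spec$tau >= 10 && spec$tau <= 20)
  expect_equal(spec$m, 3L)
  expect_s3_class(attr(spec, "ami_curve"), "ami_curve")
  expect_true(is.data.frame(attr(spec, "fnn")))
})
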