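test_that("window_series forms floor(n/window) points and discards the tail", {
  expect_equal(window_series(rep(1, 120), 60), c(1, 1))
  expect_warning(out <- window_series(stats::rnorm(59), 60), "0 data points")
  expect_length(out, 0L)
  expect_error(window_series(1:10, 0), ">= 1")
  x <- as.numeric(1:10)
  expect_equal(window_series(x, 3, "mean"), c(2, 5, 8))
  expect_equal(window_series(x, 3, "first"), c(1, 4, 7))
  # a 35,937-base series yields 598 data points at the default window
  s <- encode_spectral(generate_dna(35937, seed = 1))
  expect_length(window_series(s)$values, 598L)
})

test_that("split_series gives floor(0.15 n) to validation and test, rest to train", {
  expect_equal(unname(split_series(seq_len(598))$sizes), c(420, 89, 89))
  expect_equal(unname(split_series(seq_len(821))$sizes), c(575, 123, 123))
  expect_equal(unname(split_series(seq_len(100))$sizes), c(70, 15, 15))
  expect_error(split_series(1:2), "at least 3")
  # contiguous chronological partition
  sp <- split_series(seq_len(37))
  expect_equal(c(sp$train, sp$validation, sp$test), seq_len(37))
})

test_that("normalizations map as defined and invert to 1e-10", {
  mm <- normalize_series(c(0, 5, 10), "minmax")
  expect_equal(mm$values, c(0, 0.5, 1))
  vv <- normalize_series(c(1, 3), "variance")
  expect_equal(vv$values, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  for (mode in c("minmax", "variance")) {
    x <- stats::rnorm(50, mean = 3, sd = 2)
    nm <- normalize_series(x, mode)
    expect_equal(inverse_normalize(nm$values, nm$params), x, tolerance = 1e-10)
  }
  expect_error(normalize_series(rep(2, 5), "minmax"), "degenerate")
  expect_error(normalize_series(rep(2, 5), "variance"), "degenerate")
})

test_that("normalization statistics can be fitted on the training segment only", {
  x <- c(1, 2, 3, 10)
  nm <- normalize_series(x, "minmax", fit_on = x[1:3])
  expect_equal(nm$values[1:3], c(0, 0.5, 1))
  expect_gt(nm$values[4], 1)  # out-of-segment values may leave [0, 1]
  expect_equal(inverse_normalize(nm$values, nm$params), x, tolerance = 1e-10)
})

test_that("derive_six_series yields six aligned leakage-safe series", {
  s <- generate_dna(3000, seed = 8)
  six <- derive_six_series(s, window_len = 30)
  expect_length(six$series, 6L)
  expect_setequal(names(six$series),
                  c("spectral_minmax", "spectral_variance", "cgr_minmax",
                    "cgr_variance", "z_minmax", "z_variance"))
  lens <- vapply(six$series, function(b) length(b$values), 0L)
  expect_true(all(lens == 100L))
  tr <- seq_len(six$split_sizes[["train"]])
  for (key in c("spectral_minmax", "cgr_minmax", "z_minmax")) {
    expect_true(all(six$series[[key]]$values[tr] >= 0 - 1e-12))
    expect_true(all(six$series[[key]]$values[tr] <= 1 + 1e-12))
  }
  for (key in c("spectral_variance", "cgr_variance", "z_variance")) {
    expect_lt(abs(mean(six$series[[key]]$values[tr])), 1e-8)
    expect_lt(abs(stats::sd(six$series[[key]]$values[tr]) - 1), 1e-8)
  }
  # undoing normalization reproduces the windowed series exactly
  back <- inverse_normalize(six$series$spectral_minmax$values,
                            six$params$spectral_minmax)
  expect_equal(back, six$raw$spectral$values, tolerance = 1e-10)
})

test_that("make_supervised builds chronologically aligned lookback samples", {
  sup <- make_supervised(matrix(stats::rnorm(20), 10, 2), lookback = 8)
  expect_equal(sup$n_samples, 2L)
  sup2 <- make_supervised(matrix(as.numeric(1:5), ncol = 1), lookback = 1)
  expect_equal(sup2$targets, c(2, 3, 4, 5))
  expect_equal(as.numeric(sup2$inputs[1, 1, ]), c(1, 2, 3, 4))
  expect_error(make_supervised(matrix(1:5), lookback = 0), ">= 1")
  expect_error(make_supervised(matrix(as.numeric(1:5), ncol = 1), lookback = 5),
               "more than lookback")
  # each input block immediately precedes its target
  M <- matrix(stats::rnorm(36), 12, 3)
  sup3 <- make_supervised(M, lookback = 4, target = 2)
  for (j in seq_len(sup3$n_samples)) {
    expect_equal(sup3$inputs[, , j], M[j:(j + 3), ])
    expect_equal(sup3$targets[j], M[j + 4, 2])
  }
})

test_that("stationarity summary reports rolling statistics and drift", {
  x <- c(stats::rnorm(50), stats::rnorm(50, mean = 5))
  out <- stationarity_summary(x, window = 20)
  expect_named(out, c("index", "roll_mean", "roll_sd"))
  expect_gt(attr(out, "mean_drift"), 3)
})
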