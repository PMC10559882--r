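test_that("fractional differencing weights follow the binomial recurrence", {
  expect_equal(fracdiff_weights(0, 4), c(1, 0, 0, 0, 0))
  expect_equal(fracdiff_weights(1, 4), c(1, -1, 0, 0, 0))
  expect_equal(fracdiff_weights(0.5, 3), c(1, -0.5, -0.125, -0.0625))
})

test_that("weights match the gamma-function closed form for |d| < 0.5", {
  # c_k = Gamma(k - d) / (Gamma(k + 1) * Gamma(-d))
  for (d in c(-0.45, -0.2, 0.1, 0.3, 0.49)) {
    w <- fracdiff_weights(d, 100)
    k <- 1:100
    # Gamma(-d) is negative for d in (0, 0.5): restore its sign after lgamma
    closed <- sign(gamma(-d)) * exp(lgamma(k - d) - lgamma(k + 1) - lgamma(-d))
    expect_equal(w[-1], closed, tolerance = 1e-10)
    expect_equal(w[1], 1)
  }
})

test_that("frac_difference reduces to discrete differencing and inverts exactly", {
  expect_equal(as.numeric(frac_difference(c(1, 3, 6), 1)), c(2, 3))
  x <- stats::rnorm(200)
  expect_equal(as.numeric(frac_difference(x, 0)), x)
  for (d in c(0.3, -0.3, 0.49)) {
    w <- frac_difference(x, d)
    expect_equal(frac_integrate(as.numeric(w), d), x, tolerance = 1e-8)
  }
  # integer d round-trips through the history attribute
  w1 <- frac_difference(x, 1)
  expect_equal(frac_integrate(w1, 1), x, tolerance = 1e-8)
  w2 <- frac_difference(x, 2)
  expect_equal(frac_integrate(w2, 2), x, tolerance = 1e-8)
})

test_that("fit_arfima recovers known structure", {
  x <- generate_arfima_series(2000, d = 0.3, ar = 0.6, seed = 1)
  fit <- fit_arfima(x, p = 1, d = 0.3, q = 0)
  expect_lt(abs(fit$ar - 0.6), 0.1)

  wn <- generate_arfima_series(2000, seed = 2)
  fit0 <- fit_arfima(wn, 0, 0, 0)
  expect_lt(abs(fit0$sigma2 / stats::var(wn) - 1), 0.05)

  expect_error(fit_arfima(stats::rnorm(30), p = 2, q = 2), "too short")
})

test_that("forecasts obey closed forms", {
  wn <- generate_arfima_series(500, seed = 3, mean = 7)
  fit0 <- fit_arfima(wn, 0, 0, 0)
  expect_equal(forecast_arfima(fit0, h = 5), rep(fit0$mean, 5),
               tolerance = 1e-10)

  ar1 <- generate_arfima_series(500, ar = 0.7, seed = 4, mean = 3)
  fit1 <- fit_arfima(ar1, 1, 0, 0)
  expect_equal(forecast_arfima(fit1, h = 1),
               fit1$mean + fit1$ar * (ar1[500] - fit1$mean), tolerance = 1e-10)

  # d = 1, p = q = 0 on a linear ramp continues the ramp
  ramp <- as.numeric(1:100) * 0.5 + 2
  fitr <- fit_arfima(ramp, 0, 1, 0)
  expect_equal(forecast_arfima(fitr, h = 3), ramp[100] + 0.5 * (1:3),
               tolerance = 1e-8)

  # constant series: any (p, 0, q) fit forecasts the constant
  const <- rep(4.2, 60)
  fitc <- fit_arfima(const, 1, 0, 1)
  expect_equal(forecast_arfima(fitc, h = 4), rep(4.2, 4), tolerance = 1e-10)

  expect_error(forecast_arfima(fit0, h = 0), ">= 1")
})

test_that("rolling one-step forecasts match a manual AR(1) recursion", {
  x <- generate_arfima_series(300, ar = 0.5, seed = 5, mean = 1)
  tr <- x[1:250]; te <- x[251:300]
  fit <- fit_arfima(tr, 1, 0, 0)
  pred <- rolling_forecast_arfima(fit, te, history = tr)
  manual <- fit$mean + fit$ar * (x[250:299] - fit$mean)
  expect_equal(pred, manual, tolerance = 1e-10)
})

test_that("CSS profile over d is minimized near the true order", {
  x <- generate_arfima_series(2000, d = 0.3, seed = 6)
  dgrid <- seq(0, 0.4, by = 0.1)
  css <- vapply(dgrid, function(d) fit_arfima(x, 0, d, 0)$css, 0)
  expect_lte(abs(dgrid[which.min(css)] - 0.3), 0.1)
})

test_that("tune_arfima never validates worse than the white-noise baseline", {
  x <- generate_arfima_series(260, ar = 0.8, seed = 7, mean = 10)
  tr <- x[1:200]; va <- x[201:260]
  ctl <- pso_control(swarm_size = 6, iterations = 4, seed = 8)
  tuned <- suppressWarnings(tune_arfima(tr, va, p_max = 3, q_max = 3,
                                        control = ctl))
  base <- fit_arfima(tr, 0, 0, 0)
  base_mape <- mape(va, rolling_forecast_arfima(base, va, history = tr))
  expect_lte(tuned$val_fitness, base_mape + 1e-10)
  tuned2 <- suppressWarnings(tune_arfima(tr, va, p_max = 3, q_max = 3,
                                         control = ctl))
  expect_equal(tuned$orders, tuned2$orders)
  expect_identical(tuned$val_fitness, tuned2$val_fitness)
})

test_that("fitted models serialize to JSON with their coefficients", {
  x <- generate_arfima_series(300, ar = 0.5, seed = 9)
  fit <- fit_arfima(x, 1, 0.1, 0)
  doc <- jsonlite::fromJSON(arfima_to_json(fit))
  expect_equal(doc$p, 1)
  expect_equal(doc$d, 0.1)
  expect_equal(doc$ar, fit$ar, tolerance = 1e-12)
})
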