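test_that("conv1d performs valid cross-channel temporal convolution", {
  expect_equal(as.numeric(conv1d(c(5, -2, 7), 1)), c(5, -2, 7))
  expect_equal(as.numeric(conv1d(c(1, 2, 4), c(1, -1))), c(-1, -2))
  two <- matrix(1, 4, 2)
  kern <- array(1, dim = c(2, 2, 1))
  expect_equal(as.numeric(conv1d(two, kern)), rep(4, 3))
  expect_error(conv1d(c(1, 2), c(1, 1, 1)), "exceeds")
  expect_error(conv1d(matrix(1, 4, 2), array(1, dim = c(2, 3, 1))), "channel")
})

test_that("conv1d agrees with a brute-force triple loop", {
  set.seed(11)
  for (rep in 1:5) {
    N <- sample(1:4, 1); Tlen <- sample(4:16, 1); wd <- sample(1:3, 1)
    K <- sample(1:3, 1)
    X <- matrix(stats::rnorm(Tlen * N), Tlen, N)
    W <- array(stats::rnorm(wd * N * K), dim = c(wd, N, K))
    b <- stats::rnorm(K)
    out <- conv1d(X, W, b)
    for (k in seq_len(K)) {
      for (j in seq_len(Tlen - wd + 1)) {
        acc <- b[k]
        for (u in seq_len(wd)) {
          for (c in seq_len(N)) acc <- acc + W[u, c, k] * X[j + u - 1, c]
        }
        expect_equal(out[j, k], acc, tolerance = 1e-10)
      }
    }
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  spec <- cnn_lstm_spec(n_hn = 3, n_kernels = 2, kernel_width = 2)
  m <- init_cnn_lstm(spec, n_channels = 2, lookback = 5, seed = 9)
  X <- array(stats::rnorm(5 * 2 * 4), dim = c(5, 2, 4))
  y <- stats::rnorm(4)
  lg <- btsforecast:::nn_loss_grad(m, X, y)
  eps <- 1e-6
  for (nm in names(m$weights)) {
    w <- m$weights[[nm]]
    for (idx in seq_len(min(length(w), 4))) {
      mp <- m; mp$weights[[nm]][idx] <- mp$weights[[nm]][idx] + eps
      mm <- m; mm$weights[[nm]][idx] <- mm$weights[[nm]][idx] - eps
      num <- (btsforecast:::nn_loss_grad(mp, X, y)$loss -
                btsforecast:::nn_loss_grad(mm, X, y)$loss) / (2 * eps)
      expect_equal(lg$grads[[nm]][idx], num, tolerance = 1e-5)
    }
  }
  # the conv-free variant backpropagates correctly too
  spec2 <- cnn_lstm_spec(n_hn = 3, use_conv = FALSE)
  m2 <- init_cnn_lstm(spec2, n_channels = 2, lookback = 4, seed = 10)
  X2 <- array(stats::rnorm(4 * 2 * 3), dim = c(4, 2, 3))
  y2 <- stats::rnorm(3)
  lg2 <- btsforecast:::nn_loss_grad(m2, X2, y2)
  nm <- "Wi"; idx <- 2L
  mp <- m2; mp$weights[[nm]][idx] <- mp$weights[[nm]][idx] + eps
  mm <- m2; mm$weights[[nm]][idx] <- mm$weights[[nm]][idx] - eps
  num <- (btsforecast:::nn_loss_grad(mp, X2, y2)$loss -
            btsforecast:::nn_loss_grad(mm, X2, y2)$loss) / (2 * eps)
  expect_equal(lg2$grads[[nm]][idx], num, tolerance = 1e-5)
})

test_that("the network fits a noiseless sinusoid to small training error", {
  sup <- sinusoid_supervised(n = 100, lookback = 8)
  spec <- cnn_lstm_spec(n_tr = 200, n_hn = 8, d_tr = 0.05, n_kernels = 4,
                        kernel_width = 3)
  m <- fit_cnn_lstm(sup, spec = spec, seed = 1)
  final <- utils::tail(m$history$train_loss, 1)
  expect_lt(final, 1e-2 * stats::var(sup$targets))
  expect_lte(utils::tail(m$history$train_loss, 1), m$history$train_loss[1])
})

test_that("training is deterministic under a fixed seed", {
  sup <- sinusoid_supervised(n = 60, lookback = 6, channels = 2)
  spec <- cnn_lstm_spec(n_tr = 15, n_hn = 4, d_tr = 0.02, n_kernels = 3)
  a <- fit_cnn_lstm(sup, spec = spec, seed = 5)
  b <- fit_cnn_lstm(sup, spec = spec, seed = 5)
  expect_identical(a$weights, b$weights)
  expect_identical(a$history, b$history)
  expect_identical(predict_multi(a, sup), predict_multi(b, sup))
})

test_that("zero-epoch training warns and returns the initialization", {
  sup <- sinusoid_supervised(n = 40, lookback = 5)
  spec <- cnn_lstm_spec(n_tr = 0, n_hn = 4, n_kernels = 2)
  expect_warning(m <- fit_cnn_lstm(sup, spec = spec, seed = 2), "n_tr = 0")
  init <- init_cnn_lstm(spec, 1L, 5L, seed = btsforecast:::derive_seed(2, 1))
  expect_identical(m$weights, init$weights)
  expect_true(all(is.finite(predict_multi(m, sup))))
})

test_that("SaPt pre-training is a no-op at patience 0 and makes progress otherwise", {
  sup <- sinusoid_supervised(n = 80, lookback = 6, channels = 3)
  val <- sinusoid_supervised(n = 40, lookback = 6, channels = 3)
  spec <- cnn_lstm_spec(n_tr = 10, n_hn = 4, d_tr = 0.02, n_kernels = 3)
  m0 <- init_cnn_lstm(spec, 3L, 6L, seed = 4)
  same <- sapt_pretrain(m0, sup, val, patience = 0, seed = 1)
  expect_identical(same$weights, m0$weights)
  warm <- sapt_pretrain(m0, sup, val, patience = 2, max_epochs = 10, seed = 1)
  expect_false(identical(warm$weights, m0$weights))
  expect_length(warm$sapt_epochs, 3L)
  warm2 <- sapt_pretrain(m0, sup, val, patience = 2, max_epochs = 10, seed = 1)
  expect_identical(warm$weights, warm2$weights)
})

test_that("predict_multi checks channels and preserves sample order", {
  sup <- sinusoid_supervised(n = 50, lookback = 5, channels = 2)
  spec <- cnn_lstm_spec(n_tr = 5, n_hn = 4, n_kernels = 2)
  m <- fit_cnn_lstm(sup, spec = spec, seed = 3)
  pred <- predict_multi(m, sup)
  expect_length(pred, sup$n_samples)
  other <- sinusoid_supervised(n = 50, lookback = 5, channels = 3)
  expect_error(predict_multi(m, other), "channels")
})

test_that("hyperparameter search honours the incumbent and is reproducible", {
  sup <- sinusoid_supervised(n = 70, lookback = 6)
  val <- sinusoid_supervised(n = 30, lookback = 6)
  base <- cnn_lstm_spec(n_tr = 10, n_hn = 4, d_tr = 0.02, n_kernels = 2)
  ctl <- pso_control(swarm_size = 3, iterations = 2, seed = 6)
  tuned <- tune_cnn_lstm(sup, val, n_tr_range = c(5, 20),
                         n_hn_range = c(2, 6), log_d_tr_range = c(-2.5, -1),
                         base_spec = base, control = ctl, seed = 7)
  # fitness of the incumbent spec, computed independently
  m_inc <- fit_cnn_lstm(sup, val, base, seed = 7)
  inc_fit <- mape(val$targets, predict_multi(m_inc, val))
  expect_lte(tuned$val_fitness, inc_fit + 1e-10)
  tuned2 <- tune_cnn_lstm(sup, val, n_tr_range = c(5, 20),
                          n_hn_range = c(2, 6), log_d_tr_range = c(-2.5, -1),
                          base_spec = base, control = ctl, seed = 7)
  expect_identical(tuned$val_fitness, tuned2$val_fitness)
  expect_identical(unclass(tuned$spec), unclass(tuned2$spec))
})
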