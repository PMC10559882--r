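#' CNN-LSTM hyperparameter specification
#'
#' The three searched hyperparameters are the training epoch count `n_tr`,
#' the LSTM hidden-unit count `n_hn`, and the learning rate `d_tr`. The
#' architecture is the smallest consistent with a 1-D convolutional
#' recurrent forecaster: a valid (no-padding) cross-channel temporal
#' convolution layer, an LSTM over the feature-map sequence, and a linear
#' head to one output; training is mini-batch stochastic gradient descent
#' at fixed rate `d_tr` on mean squared one-step error.
#'
#' @param n_tr Training epochs (integer >= 0).
#' @param n_hn LSTM hidden units (integer >= 1).
#' @param d_tr Learning rate (> 0).
#' @param n_kernels Number of convolution kernels.
#' @param kernel_width Temporal width of each kernel.
#' @param use_conv If `FALSE` the convolution layer is dropped and the raw
#'   lookback block feeds the LSTM directly (ablation switch).
#' @param batch_size Mini-batch size for SGD.
#' @return List of class `cnn_lstm_spec`.
#' @export
cnn_lstm_spec <- function(n_tr = 100L, n_hn = 16L, d_tr = 0.01,
                          n_kernels = 16L, kernel_width = 3L,
                          use_conv = TRUE, batch_size = 16L) {
  if (n_tr < 0) stop_arg("`n_tr` must be >= 0")
  if (n_hn < 1) stop_arg("`n_hn` must be >= 1")
  if (d_tr <= 0) stop_arg("`d_tr` must be > 0")
  if (kernel_width < 1) stop_arg("`kernel_width` must be >= 1")
  structure(list(n_tr = as.integer(n_tr), n_hn = as.integer(n_hn),
                 d_tr = d_tr, n_kernels = as.integer(n_kernels),
                 kernel_width = as.integer(kernel_width),
                 use_conv = isTRUE(use_conv),
                 batch_size = as.integer(batch_size)),
            class = "cnn_lstm_spec")
}

#' One-dimensional cross-channel temporal convolution
#'
#' Valid (no-padding) convolution in the deep-learning convention (cross-
#' correlation, no kernel flip): for kernel k,
#' C_k\[j\] = sum over lags u and channels c of W_k\[u, c\] * X\[j + u - 1, c\].
#' Output length is T - width + 1.
#'
#' @param block T x N numeric matrix (lookback window, one column per
#'   channel), or a numeric vector for a single channel.
#' @param kernels width x N x K array (or width-length vector for one
#'   kernel over one channel).
#' @param bias Length-K bias (default zeros).
#' @return (T - width + 1) x K matrix of feature maps.
#' @examples
#' conv1d(c(1, 2, 4), c(1, -1))  # -1 -2
#' @export
conv1d <- function(block, kernels, bias = NULL) {
  if (is.vector(block)) block <- matrix(block, ncol = 1L)
  if (is.vector(kernels)) kernels <- array(kernels, dim = c(length(kernels), 1L, 1L))
  if (length(dim(kernels)) == 2L) {
    kernels <- array(kernels, dim = c(dim(kernels), 1L))
  }
  Tlen <- nrow(block); N <- ncol(block)
  wd <- dim(kernels)[1]; K <- dim(kernels)[3]
  if (dim(kernels)[2] != N) stop_arg("kernel channel count %d != input channels %d",
                                     dim(kernels)[2], N)
  if (wd > Tlen) stop_arg("kernel width %d exceeds window length %d", wd, Tlen)
  if (is.null(bias)) bias <- numeric(K)
  L <- Tlen - wd + 1L
  out <- matrix(0, L, K)
  for (k in seq_len(K)) {
    for (j in seq_len(L)) {
      out[j, k] <- sum(kernels[, , k] * block[j:(j + wd - 1L), , drop = FALSE]) +
        bias[k]
    }
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Initialize all network weights from a seed. Uniform(-r, r) with
# r = 1/sqrt(fan_in); LSTM forget-gate bias starts at 1 (standard).
init_cnn_lstm <- function(spec, n_channels, lookback, seed = 1L) {
  stopifnot(inherits(spec, "cnn_lstm_spec"))
  if (spec$use_conv && spec$kernel_width > lookback) {
    stop_arg("kernel width %d exceeds lookback %d", spec$kernel_width, lookback)
  }
  K <- if (spec$use_conv) spec$n_kernels else n_channels
  H <- spec$n_hn
  wN <- spec$kernel_width * n_channels
  with_seed(seed, {
    u <- function(nr, nc, fan) matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan),
                                      nr, nc)
    wts <- list()
    if (spec$use_conv) {
      wts$Wc <- u(spec$n_kernels, wN, wN)
      wts$bc <- numeric(spec$n_kernels)
    }
    for (g in c("i", "f", "o", "g")) {
      wts[[paste0("W", g)]] <- u(H, K, K)
      wts[[paste0("U", g)]] <- u(H, H, H)
      wts[[paste0("b", g)]] <- if (g == "f") rep(1, H) else numeric(H)
    }
    wts$v <- as.numeric(u(H, 1L, H))
    wts$b_y <- 0
    structure(list(spec = spec, n_channels = n_channels, lookback = lookback,
                   weights = wts, seed = seed, history = NULL),
              class = "cnn_lstm_model")
  })
}

#' @export
print.cnn_lstm_model <- function(x, ...) {
  cat(sprintf("<cnn_lstm_model> channels=%d lookback=%d conv=%s(K=%d,w=%d) hidden=%d\n",
              x$n_channels, x$lookback,
              if (x$spec$use_conv) "yes" else "no",
              x$spec$n_kernels, x$spec$kernel_width, x$spec$n_hn))
  invisible(x)
}

# Row indices into the flattened (T*N) sample vector for conv offset j.
conv_row_idx <- function(Tlen, N, wd, j) {
  as.vector(outer(j:(j + wd - 1L), (seq_len(N) - 1L) * Tlen, `+`))
}

# Batched forward pass. X: T x N x B array. Returns predictions and, when
# `cache`, everything the backward pass needs.
nn_forward <- function(model, X, cache = FALSE) {
  spec <- model$spec; wts <- model$weights
  Tlen <- dim(X)[1]; N <- dim(X)[2]; B <- dim(X)[3]
  Xm <- matrix(X, Tlen * N, B)
  if (spec$use_conv) {
    wd <- spec$kernel_width
    L <- Tlen - wd + 1L
    xs <- vector("list", L)
    zs <- vector("list", L)
    for (j in seq_len(L)) {
      zj <- Xm[conv_row_idx(Tlen, N, wd, j), , drop = FALSE]
      zs[[j]] <- zj
      xs[[j]] <- wts$Wc %*% zj + wts$bc
    }
  } else {
    L <- Tlen
    xs <- lapply(seq_len(L), function(j) matrix(X[j, , ], N, B))
    zs <- NULL
  }
  H <- spec$n_hn
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  st <- if (cache) vector("list", L) else NULL
  for (t in seq_len(L)) {
    xt <- xs[[t]]
    ai <- wts$Wi %*% xt + wts$Ui %*% h + wts$bi
    af <- wts$Wf %*% xt + wts$Uf %*% h + wts$bf
    ao <- wts$Wo %*% xt + wts$Uo %*% h + wts$bo
    ag <- wts$Wg %*% xt + wts$Ug %*% h + wts$bg
    gi <- sigmoid(ai); gf <- sigmoid(af); go <- sigmoid(ao); gg <- tanh(ag)
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev_t <- h
    h <- go * tc
    if (cache) {
      st[[t]] <- list(xt = xt, gi = gi, gf = gf, go = go, gg = gg,
                      c_prev = c_prev, cc = cc, tc = tc, h_prev = h_prev_t)
    }
  }
  yhat <- as.numeric(crossprod(wts$v, h)) + wts$b_y
  if (!cache) return(list(yhat = yhat))
  list(yhat = yhat, h_last = h, states = st, zs = zs, L = L, B = B,
       Tlen = Tlen, N = N)
}

# Batched backward pass for mean-squared-error loss; returns gradient list
# matching the weight list. dy: dLoss/dyhat (length B).
nn_backward <- function(model, fw, dy) {
  spec <- model$spec; wts <- model$weights
  H <- spec$n_hn; B <- fw$B; L <- fw$L
  g <- lapply(wts, function(w) if (is.matrix(w)) matrix(0, nrow(w), ncol(w))
              else numeric(length(w)))
  g$v <- as.numeric(fw$h_last %*% dy)
  g$b_y <- sum(dy)
  dh <- wts$v %*% matrix(dy, 1L, B)  # H x B
  dc <- matrix(0, H, B)
  dxs <- vector("list", L)
  for (t in rev(seq_len(L))) {
    s <- fw$states[[t]]
    do_ <- dh * s$tc
    dao <- do_ * s$go * (1 - s$go)
    dc <- dc + dh * s$go * (1 - s$tc^2)
    dai <- (dc * s$gg) * s$gi * (1 - s$gi)
    dag <- (dc * s$gi) * (1 - s$gg^2)
    daf <- (dc * s$c_prev) * s$gf * (1 - s$gf)
    g$Wi <- g$Wi + tcrossprod(dai, s$xt); g$Ui <- g$Ui + tcrossprod(dai, s$h_prev)
    g$bi <- g$bi + rowSums(dai)
    g$Wf <- g$Wf + tcrossprod(daf, s$xt); g$Uf <- g$Uf + tcrossprod(daf, s$h_prev)
    g$bf <- g$bf + rowSums(daf)
    g$Wo <- g$Wo + tcrossprod(dao, s$xt); g$Uo <- g$Uo + tcrossprod(dao, s$h_prev)
    g$bo <- g$bo + rowSums(dao)
    g$Wg <- g$Wg + tcrossprod(dag, s$xt); g$Ug <- g$Ug + tcrossprod(dag, s$h_prev)
    g$bg <- g$bg + rowSums(dag)
    dxs[[t]] <- crossprod(wts$Wi, dai) + crossprod(wts$Wf, daf) +
      crossprod(wts$Wo, dao) + crossprod(wts$Wg, dag)
    dh <- crossprod(wts$Ui, dai) + crossprod(wts$Uf, daf) +
      crossprod(wts$Uo, dao) + crossprod(wts$Ug, dag)
    dc <- dc * s$gf
  }
  if (spec$use_conv) {
    for (t in seq_len(L)) {
      g$Wc <- g$Wc + tcrossprod(dxs[[t]], fw$zs[[t]])
      g$bc <- g$bc + rowSums(dxs[[t]])
    }
  }
  g
}

nn_loss_grad <- function(model, X, y) {
  fw <- nn_forward(model, X, cache = TRUE)
  B <- fw$B
  resid <- fw$yhat - y
  loss <- mean(resid^2)
  grads <- nn_backward(model, fw, 2 * resid / B)
  list(loss = loss, grads = grads)
}

# One SGD epoch over shuffled mini-batches (uses the current RNG stream).
sgd_epoch <- function(model, sup, lr, batch_size) {
  S <- sup$n_samples
  ord <- sample.int(S)
  total <- 0
  for (start in seq(1L, S, by = batch_size)) {
    idx <- ord[start:min(start + batch_size - 1L, S)]
    X <- sup$inputs[, , idx, drop = FALSE]
    lg <- nn_loss_grad(model, X, sup$targets[idx])
    if (!is.finite(lg$loss)) return(list(model = model, loss = NaN))
    for (nm in names(lg$grads)) {
      model$weights[[nm]] <- model$weights[[nm]] - lr * lg$grads[[nm]]
    }
    total <- total + lg$loss * length(idx)
  }
  list(model = model, loss = total / S)
}

# Mean squared error of a model on a supervised set.
nn_mse <- function(model, sup) {
  fw <- nn_forward(model, sup$inputs)
  mean((fw$yhat - sup$targets)^2)
}

#' Train the CNN-LSTM forecaster
#'
#' Minimizes mean squared one-step error for `n_tr` epochs of mini-batch
#' SGD at fixed learning rate `d_tr`. Per-epoch training and validation
#' loss are recorded. Fully deterministic under `seed` (initialization and
#' batch shuffles both flow from it). With `n_tr = 0` the untouched
#' initialization is returned with a warning.
#'
#' @param train,val `supervised_set` objects (see [make_supervised()]);
#'   `val` may be `NULL`.
#' @param spec A [cnn_lstm_spec()].
#' @param seed Integer seed.
#' @param model Optional warm-start model (e.g. from [sapt_pretrain()]);
#'   its weights are fine-tuned instead of a fresh initialization.
#' @return A `cnn_lstm_model` with a `history` data frame (epoch,
#'   train_loss, val_loss).
#' @export
fit_cnn_lstm <- function(train, val = NULL, spec = cnn_lstm_spec(),
                         seed = 1L, model = NULL) {
  stopifnot(inherits(train, "supervised_set"))
  if (is.null(model)) {
    model <- init_cnn_lstm(spec, train$n_channels, train$lookback,
                           seed = derive_seed(seed, 1L))
  } else {
    stopifnot(inherits(model, "cnn_lstm_model"))
    if (model$n_channels != train$n_channels) {
      stop_arg("warm-start model has %d channels, data has %d",
               model$n_channels, train$n_channels)
    }
    model$spec <- spec
  }
  if (spec$n_tr == 0L) {
    warning("n_tr = 0: returning initialization without training")
    model$history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                                val_loss = numeric(0))
    return(model)
  }
  with_seed(derive_seed(seed, 2L), {
    hist <- matrix(NA_real_, spec$n_tr, 2L)
    for (ep in seq_len(spec$n_tr)) {
      step <- sgd_epoch(model, train, spec$d_tr, spec$batch_size)
      if (!is.finite(step$loss)) {
        stop_arg("training diverged (non-finite loss) at epoch %d", ep)
      }
      model <- step$model
      hist[ep, 1L] <- step$loss
      hist[ep, 2L] <- if (!is.null(val)) nn_mse(model, val) else NA_real_
    }
    model$history <- data.frame(epoch = seq_len(spec$n_tr),
                                train_loss = hist[, 1L],
                                val_loss = hist[, 2L])
    model
  })
}

# Zero out all channels except `keep` in a supervised set.
mask_channels <- function(sup, keep) {
  masked <- sup
  drop_idx <- setdiff(seq_len(sup$n_channels), keep)
  if (length(drop_idx) > 0L) masked$inputs[, drop_idx, ] <- 0
  masked
}

#' Self-adaptive per-channel pre-training (SaPt)
#'
#' Warm-starts the network by pre-training it on each input channel in turn
#' (all other channels zero-masked), with the epoch count for each channel
#' chosen adaptively by early stopping: training on a channel stops once its
#' validation loss has failed to improve for `patience` consecutive epochs
#' (or at `max_epochs`), and the best-validation weights are carried to the
#' next channel. `patience = 0` disables pre-training and returns the model
#' unchanged. The returned model is the initialization for joint
#' fine-tuning with [fit_cnn_lstm()].
#'
#' @param model A `cnn_lstm_model` (fresh initialization or otherwise).
#' @param train,val `supervised_set` objects over all channels.
#' @param patience Early-stopping patience in epochs (0 = no-op).
#' @param max_epochs Cap on pre-training epochs per channel.
#' @param seed Integer seed for batch shuffling.
#' @return The warm-started `cnn_lstm_model`; the per-channel epoch counts
#'   used are in its `sapt_epochs` field.
#' @export
sapt_pretrain <- function(model, train, val, patience = 3L, max_epochs = 50L,
                          seed = 1L) {
  stopifnot(inherits(model, "cnn_lstm_model"),
            inherits(train, "supervised_set"))
  if (patience <= 0L) {
    model$sapt_epochs <- integer(0)
    return(model)
  }
  lr <- model$spec$d_tr
  bs <- model$spec$batch_size
  epochs_used <- integer(train$n_channels)
  with_seed(derive_seed(seed, 3L), {
    for (ch in seq_len(train$n_channels)) {
      tr_m <- mask_channels(train, ch)
      va_m <- mask_channels(val, ch)
      best <- nn_mse(model, va_m)
      best_w <- model$weights
      stall <- 0L
      ep <- 0L
      while (ep < max_epochs && stall < patience) {
        ep <- ep + 1L
        step <- sgd_epoch(model, tr_m, lr, bs)
        if (!is.finite(step$loss)) break
        model <- step$model
        vl <- nn_mse(model, va_m)
        if (vl < best - 1e-12) {
          best <- vl
          best_w <- model$weights
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      model$weights <- best_w
      epochs_used[ch] <- ep
    }
    model$sapt_epochs <- epochs_used
    model
  })
}

#' Forecasts of the multi-sequence module
#'
#' One forecast per supervised sample, in chronological order, in the
#' (normalized) units the network was trained in.
#'
#' @param model A trained `cnn_lstm_model`.
#' @param sup A `supervised_set` with the same channel count.
#' @return Numeric vector of forecasts, length `sup$n_samples`.
#' @export
predict_multi <- function(model, sup) {
  stopifnot(inherits(model, "cnn_lstm_model"), inherits(sup, "supervised_set"))
  if (sup$n_channels != model$n_channels) {
    stop_arg("model expects %d channels, data has %d",
             model$n_channels, sup$n_channels)
  }
  nn_forward(model, sup$inputs)$yhat
}

#' PSO search of CNN-LSTM hyperparameters
#'
#' Particle-swarm search over epochs `n_tr` (integer), hidden units `n_hn`
#' (integer) and learning rate `d_tr` (searched on log10 scale). Fitness of
#' a candidate is the validation MAPE of the trained network (RMSE when the
#' validation targets contain zeros, as normalized targets may). The
#' defaults of [cnn_lstm_spec()] are seeded as the incumbent particle.
#'
#' @param train,val `supervised_set` objects.
#' @param n_tr_range,n_hn_range Integer search intervals.
#' @param log_d_tr_range Search interval for log10 of the learning rate.
#' @param base_spec Template spec supplying the non-searched fields.
#' @param control A [pso_control()].
#' @param seed Seed used for every candidate training run.
#' @return List with `spec` (best [cnn_lstm_spec()]), `model` (trained at
#'   the best spec), `val_fitness`, `history`.
#' @export
tune_cnn_lstm <- function(train, val, n_tr_range = c(50, 300),
                          n_hn_range = c(4, 64), log_d_tr_range = c(-4, -1),
                          base_spec = cnn_lstm_spec(), control = pso_control(),
                          seed = 1L) {
  stopifnot(inherits(train, "supervised_set"), inherits(val, "supervised_set"))
  use_mape <- all(val$targets != 0)
  make_spec <- function(pos) {
    cnn_lstm_spec(n_tr = as.integer(round(pos[1])),
                  n_hn = as.integer(round(pos[2])),
                  d_tr = 10^pos[3],
                  n_kernels = base_spec$n_kernels,
                  kernel_width = base_spec$kernel_width,
                  use_conv = base_spec$use_conv,
                  batch_size = base_spec$batch_size)
  }
  objective <- function(pos) {
    m <- fit_cnn_lstm(train, val, make_spec(pos), seed = seed)
    pred <- predict_multi(m, val)
    if (use_mape) mape(val$targets, pred) else
      sqrt(mean((val$targets - pred)^2))
  }
  inc <- c(min(max(base_spec$n_tr, n_tr_range[1]), n_tr_range[2]),
           min(max(base_spec$n_hn, n_hn_range[1]), n_hn_range[2]),
           min(max(log10(base_spec$d_tr), log_d_tr_range[1]),
               log_d_tr_range[2]))
  res <- pso_optimize(objective,
                      lower = c(n_tr_range[1], n_hn_range[1], log_d_tr_range[1]),
                      upper = c(n_tr_range[2], n_hn_range[2], log_d_tr_range[2]),
                      integer_mask = c(TRUE, TRUE, FALSE),
                      control = control, incumbent = inc)
  best_spec <- make_spec(res$position)
  list(spec = best_spec,
       model = fit_cnn_lstm(train, val, best_spec, seed = seed),
       val_fitness = res$fitness, history = res$history)
}
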