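#' Convex fusion weights for the two module outputs
#'
#' @param w_ar,w_lstm Non-negative weights summing to 1 (scalars, or
#'   per-timestep vectors for elementwise fusion).
#' @return List of class `ensemble_weights`.
#' @export
ensemble_weights <- function(w_ar, w_lstm) {
  if (any(w_ar < 0) || any(w_ar > 1) || any(w_lstm < 0) || any(w_lstm > 1)) {
    stop_arg("weights must lie in [0, 1]")
  }
  if (any(abs(w_ar + w_lstm - 1) > 1e-8)) {
    stop_arg("weights must sum to 1 (elementwise)")
  }
  structure(list(w_ar = w_ar, w_lstm = w_lstm), class = "ensemble_weights")
}

#' Fuse single-sequence and multi-sequence outputs
#'
#' Elementwise convex combination
#' C_t = W_AR * O_AR_t + W_LSTM * O_LSTM_t. Weights are scalar per model by
#' default; per-timestep weight vectors are accepted for elementwise fusion.
#'
#' @param o_ar,o_lstm Aligned forecast series of the two modules.
#' @param weights An [ensemble_weights()] object.
#' @return Fused forecast series.
#' @export
weighted_fuse <- function(o_ar, o_lstm, weights) {
  stopifnot(inherits(weights, "ensemble_weights"))
  check_numeric_vector(o_ar, "o_ar"); check_numeric_vector(o_lstm, "o_lstm")
  if (length(o_ar) != length(o_lstm)) stop_arg("module output lengths differ")
  if (length(weights$w_ar) > 1L && length(weights$w_ar) != length(o_ar)) {
    stop_arg("per-timestep weights must match the output length")
  }
  weights$w_ar * o_ar + weights$w_lstm * o_lstm
}

#' Learn fusion weights on validation data
#'
#' Brute-force grid search (step 0.01, exact within the grid) for the
#' scalar w in \[0, 1\] minimizing validation MSE of
#' w * O_AR + (1 - w) * O_LSTM. Because w = 0 and w = 1 are on the grid,
#' the fused validation MSE can never exceed either component's by more
#' than the grid tolerance.
#'
#' @param o_ar_val,o_lstm_val Validation forecasts of the two modules.
#' @param y_val Validation truths.
#' @param step Grid step.
#' @return An [ensemble_weights()] object.
#' @export
learn_weights <- function(o_ar_val, o_lstm_val, y_val, step = 0.01) {
  check_numeric_vector(o_ar_val, "o_ar_val")
  check_numeric_vector(o_lstm_val, "o_lstm_val")
  check_numeric_vector(y_val, "y_val")
  if (length(o_ar_val) != length(y_val) || length(o_lstm_val) != length(y_val)) {
    stop_arg("validation series lengths differ")
  }
  if (max(abs(o_ar_val - o_lstm_val)) < 1e-12) {
    warning("module outputs are identical on validation; using equal weights")
    return(ensemble_weights(0.5, 0.5))
  }
  grid <- seq(0, 1, by = step)
  mse <- vapply(grid, function(w) {
    mean((w * o_ar_val + (1 - w) * o_lstm_val - y_val)^2)
  }, 0)
  w <- grid[which.min(mse)]
  ensemble_weights(w, 1 - w)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. The four ablation switches
#' mirror the framework's separable modules: `use_sapt` (per-channel
#' pre-training), `use_conv` (the 1-D convolution layer), `use_ar` (the
#' ARFIMA branch), `use_tuning` (the particle-swarm searches; when off, the
#' default orders/spec are used as-is).
#'
#' @param window_len,aggregate,lookback,cgr_mode See [derive_six_series()]
#'   and [make_supervised()].
#' @param target_encoding Which encoding's windowed series is forecast and
#'   scored (in its original units): `"spectral"`, `"cgr"` or `"z"`.
#' @param use_sapt,use_conv,use_ar,use_tuning Ablation switches.
#' @param default_arfima_orders (p, d, q) used when `use_tuning = FALSE`.
#' @param arfima_pso,cnn_pso [pso_control()] budgets of the two searches.
#' @param cnn_spec Base [cnn_lstm_spec()].
#' @param n_tr_range,n_hn_range,log_d_tr_range CNN-LSTM search ranges.
#' @param p_max,q_max,d_range ARFIMA search ranges.
#' @param sapt_patience,sapt_max_epochs Pre-training early-stop settings.
#' @param seed Master seed; every stage seed is derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(window_len = 60L, aggregate = "mean",
                            lookback = 8L, cgr_mode = "norm",
                            target_encoding = "spectral",
                            use_sapt = TRUE, use_conv = TRUE, use_ar = TRUE,
                            use_tuning = TRUE,
                            default_arfima_orders = c(1, 0, 0),
                            arfima_pso = pso_control(swarm_size = 6L,
                                                     iterations = 4L),
                            cnn_pso = pso_control(swarm_size = 4L,
                                                  iterations = 3L),
                            cnn_spec = cnn_lstm_spec(n_tr = 40L, n_hn = 8L,
                                                     d_tr = 0.02,
                                                     n_kernels = 8L),
                            n_tr_range = c(20, 60), n_hn_range = c(4, 16),
                            log_d_tr_range = c(-3, -1),
                            p_max = 3L, q_max = 3L, d_range = c(-0.49, 0.49),
                            sapt_patience = 2L, sapt_max_epochs = 15L,
                            seed = 1L) {
  structure(list(window_len = window_len, aggregate = aggregate,
                 lookback = as.integer(lookback), cgr_mode = cgr_mode,
                 target_encoding = match.arg(target_encoding,
                                             c("spectral", "cgr", "z")),
                 use_sapt = use_sapt, use_conv = use_conv, use_ar = use_ar,
                 use_tuning = use_tuning,
                 default_arfima_orders = default_arfima_orders,
                 arfima_pso = arfima_pso, cnn_pso = cnn_pso,
                 cnn_spec = cnn_spec, n_tr_range = n_tr_range,
                 n_hn_range = n_hn_range, log_d_tr_range = log_d_tr_range,
                 p_max = p_max, q_max = q_max, d_range = d_range,
                 sapt_patience = sapt_patience,
                 sapt_max_epochs = sapt_max_epochs,
                 seed = seed), class = "pipeline_config")
}

#' Name of the model variant implied by the ablation switches
#' @param config A [pipeline_config()].
#' @return Character model name, e.g. "SaPt-CNN-LSTM-AR-EA".
#' @export
model_variant_name <- function(config) {
  parts <- c(if (config$use_sapt) "SaPt", if (config$use_conv) "CNN",
             "LSTM", if (config$use_ar) "AR", if (config$use_tuning) "EA")
  paste(parts, collapse = "-")
}

# Subset a supervised set by sample indices (chronological order kept).
subset_supervised <- function(sup, idx) {
  out <- sup
  out$inputs <- sup$inputs[, , idx, drop = FALSE]
  out$targets <- sup$targets[idx]
  out$n_samples <- length(idx)
  out
}

# OLS calibration of the target series onto one channel, fitted on the
# training segment: returns (a, b) of yhat_target = a + b * x_channel.
fit_calibration <- function(x_train, y_train) {
  if (stats::sd(x_train) < 1e-10) {
    return(c(a = mean(y_train), b = 0))
  }
  b <- stats::cov(x_train, y_train) / stats::var(x_train)
  c(a = mean(y_train) - b * mean(x_train), b = b)
}

#' Run the full hybrid-ensemble pipeline
#'
#' For each input sequence: derive the six windowed/normalized series; fit
#' (optionally PSO-tuned) ARFIMA models per channel, map each channel's
#' rolling one-step forecasts onto the target scale by a training-segment
#' OLS calibration, and fuse them with inverse-validation-MAPE weights into
#' O_AR; train the (optionally SaPt-warm-started, optionally tuned)
#' CNN-LSTM on all six channels for O_LSTM; learn the convex fusion weight
#' on the validation segment; score the fused test forecasts with the full
#' metrics suite against naive-persistence and fixed-order ARIMA baselines.
#' A failing sequence is recorded with its error and the rest continue.
#'
#' @param seqs A [dna_seq], a list of them, or a character vector of
#'   sequences.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: writes `report.json` and per-sequence
#'   forecast CSVs there.
#' @return List of class `pipeline_report`: `model`, `config` echo, and
#'   `sequences` (one entry per input with splits, tuned hyperparameters,
#'   weights, per-split metrics, baselines and DM test).
#' @export
run_pipeline <- function(seqs, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  if (is.character(seqs)) {
    seqs <- lapply(seq_along(seqs), function(i) dna_seq(paste0("seq", i), seqs[i]))
  }
  results <- lapply(seq_along(seqs), function(i) {
    sq <- seqs[[i]]
    tryCatch(run_pipeline_one(sq, config, derive_seed(config$seed, i * 101L)),
             error = function(e) list(id = sq$id, error = conditionMessage(e)))
  })
  names(results) <- vapply(seqs, `[[`, character(1), "id")
  report <- structure(list(model = model_variant_name(config),
                           seed = config$seed,
                           target_encoding = config$target_encoding,
                           window_len = config$window_len,
                           lookback = config$lookback,
                           sequences = results),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(report_to_json(report), file.path(out_dir, "report.json"))
    for (nm in names(report$sequences)) {
      r <- report$sequences[[nm]]
      if (!is.null(r$forecasts)) {
        utils::write.csv(r$forecasts,
                         file.path(out_dir, paste0(nm, "_forecasts.csv")),
                         row.names = FALSE)
      }
    }
  }
  report
}

run_pipeline_one <- function(sq, config, seed) {
  six <- derive_six_series(sq, window_len = config$window_len,
                           aggregate = config$aggregate,
                           cgr_mode = config$cgr_mode)
  sizes <- six$split_sizes
  n_train <- sizes[["train"]]; n_val <- sizes[["validation"]]
  n_test <- sizes[["test"]]
  L <- n_train + n_val + n_test
  y_raw <- six$raw[[config$target_encoding]]$values
  idx_train <- seq_len(n_train)
  idx_val <- n_train + seq_len(n_val)
  idx_test <- n_train + n_val + seq_len(n_test)
  Tlb <- config$lookback
  if (n_train <= Tlb + 5L) stop_arg("training segment too short for lookback")
  chan_names <- names(six$series)
  M <- vapply(six$series, function(s) s$values, numeric(L))

  # ---- single-sequence (ARFIMA) branch -------------------------------
  ar_branch <- NULL
  if (config$use_ar) {
    per_chan <- lapply(seq_along(chan_names), function(ci) {
      x <- M[, ci]
      tr <- x[idx_train]; va <- x[idx_val]; te <- x[idx_test]
      if (config$use_tuning) {
        ctl <- config$arfima_pso
        ctl$seed <- derive_seed(seed, 10L + ci)
        tuned <- tune_arfima(tr, va, p_max = config$p_max,
                             q_max = config$q_max, d_range = config$d_range,
                             control = ctl)
        fit <- tuned$fit
      } else {
        o <- config$default_arfima_orders
        fit <- fit_arfima(tr, o[1], o[2], o[3])
      }
      pred_all <- rolling_forecast_arfima(fit, c(va, te), history = tr)
      pred_tr <- rolling_forecast_arfima(fit, tr[-1], history = tr[1])
      cal <- fit_calibration(tr, y_raw[idx_train])
      list(orders = c(p = fit$p, d = fit$d, q = fit$q),
           cal = cal,
           pred_train = cal[1] + cal[2] * c(tr[1], pred_tr),
           pred_val = cal[1] + cal[2] * pred_all[seq_len(n_val)],
           pred_test = cal[1] + cal[2] * pred_all[n_val + seq_len(n_test)])
    })
    names(per_chan) <- chan_names
    val_mape <- vapply(per_chan, function(pc) {
      mape(y_raw[idx_val], pc$pred_val)
    }, 0)
    wts <- 1 / pmax(val_mape, 1e-8)
    wts <- wts / sum(wts)
    fuse_chan <- function(field) {
      Reduce(`+`, Map(function(pc, w) w * pc[[field]], per_chan, wts))
    }
    ar_branch <- list(per_chan = per_chan, weights = wts,
                      o_train = fuse_chan("pred_train"),
                      o_val = fuse_chan("pred_val"),
                      o_test = fuse_chan("pred_test"))
  }

  # ---- multi-sequence (CNN-LSTM) branch ------------------------------
  target_chan <- paste0(config$target_encoding, "_minmax")
  tci <- match(target_chan, chan_names)
  sup_full <- make_supervised(M, lookback = Tlb, target = tci)
  pos <- Tlb + seq_len(sup_full$n_samples)  # target position of each sample
  sup_tr <- subset_supervised(sup_full, which(pos <= n_train))
  sup_va <- subset_supervised(sup_full, which(pos > n_train &
                                                pos <= n_train + n_val))
  sup_te <- subset_supervised(sup_full, which(pos > n_train + n_val))
  base_spec <- config$cnn_spec
  base_spec$use_conv <- config$use_conv
  cnn_seed <- derive_seed(seed, 50L)
  if (config$use_tuning) {
    ctl <- config$cnn_pso
    ctl$seed <- derive_seed(seed, 51L)
    tuned_cnn <- tune_cnn_lstm(sup_tr, sup_va,
                               n_tr_range = config$n_tr_range,
                               n_hn_range = config$n_hn_range,
                               log_d_tr_range = config$log_d_tr_range,
                               base_spec = base_spec, control = ctl,
                               seed = cnn_seed)
    spec <- tuned_cnn$spec
  } else {
    spec <- base_spec
  }
  model <- init_cnn_lstm(spec, sup_tr$n_channels, Tlb,
                         seed = derive_seed(cnn_seed, 1L))
  if (config$use_sapt) {
    model <- sapt_pretrain(model, sup_tr, sup_va,
                           patience = config$sapt_patience,
                           max_epochs = config$sapt_max_epochs,
                           seed = derive_seed(cnn_seed, 4L))
  }
  model <- fit_cnn_lstm(sup_tr, sup_va, spec, seed = cnn_seed, model = model)
  tpar <- six$params[[target_chan]]
  lstm_pred <- function(sup) {
    inverse_normalize(predict_multi(model, sup), tpar)
  }
  o_lstm_val <- lstm_pred(sup_va)
  o_lstm_test <- lstm_pred(sup_te)
  o_lstm_train <- lstm_pred(sup_tr)

  # ---- fusion --------------------------------------------------------
  y_val <- y_raw[idx_val]; y_test <- y_raw[idx_test]
  if (config$use_ar) {
    w <- learn_weights(ar_branch$o_val, o_lstm_val, y_val)
    fused_val <- weighted_fuse(ar_branch$o_val, o_lstm_val, w)
    fused_test <- weighted_fuse(ar_branch$o_test, o_lstm_test, w)
  } else {
    w <- ensemble_weights(0, 1)
    fused_val <- o_lstm_val
    fused_test <- o_lstm_test
  }

  # ---- evaluation ----------------------------------------------------
  train_pos <- Tlb + seq_len(sup_tr$n_samples)
  y_train_eval <- y_raw[train_pos]
  fused_train <- if (config$use_ar) {
    weighted_fuse(ar_branch$o_train[train_pos], o_lstm_train, w)
  } else o_lstm_train
  metrics <- list(train = eval_report(y_train_eval, fused_train),
                  validation = eval_report(y_val, fused_val),
                  test = eval_report(y_test, fused_test))

  # baselines on the test segment: naive persistence and fixed ARIMA(1,0,0)
  naive_test <- y_raw[idx_test - 1L]
  arima_fit <- fit_arfima(y_raw[idx_train], 1, 0, 0)
  arima_test <- rolling_forecast_arfima(arima_fit, c(y_val, y_test),
                                        history = y_raw[idx_train])
  arima_test <- arima_test[n_val + seq_len(n_test)]
  baselines <- list(
    naive = eval_report(y_test, naive_test),
    arima_1_0_0 = eval_report(y_test, arima_test)
  )
  dm_naive <- dm_test(y_test - fused_test, y_test - naive_test)
  p_mape_naive <- accuracy_growth(baselines$naive$mape, metrics$test$mape)

  list(
    id = sq$id, n_bases = sq$n, n_points = L,
    splits = as.list(sizes),
    arfima = if (config$use_ar) {
      list(orders = lapply(ar_branch$per_chan, `[[`, "orders"),
           channel_weights = as.list(ar_branch$weights))
    } else NULL,
    cnn_spec = unclass(spec),
    sapt_epochs = if (config$use_sapt) model$sapt_epochs else integer(0),
    fusion = list(w_ar = w$w_ar, w_lstm = w$w_lstm),
    metrics = metrics,
    baselines = baselines,
    dm_vs_naive = list(statistic = dm_naive$statistic,
                       reject_99 = unname(dm_naive$reject["99"])),
    p_mape_vs_naive = p_mape_naive,
    forecasts = data.frame(index = c(idx_val, idx_test),
                           split = rep(c("validation", "test"),
                                       c(n_val, n_test)),
                           observed = c(y_val, y_test),
                           fused = c(fused_val, fused_test),
                           o_ar = if (config$use_ar)
                             c(ar_branch$o_val, ar_branch$o_test) else
                               rep(NA_real_, n_val + n_test),
                           o_lstm = c(o_lstm_val, o_lstm_test)),
    seed = seed
  )
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic serialization (no timestamps): identical runs produce
#' byte-identical JSON.
#'
#' @param report A `pipeline_report`.
#' @return JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  stripped <- unclass(report)
  stripped$sequences <- lapply(stripped$sequences, function(r) {
    r$forecasts <- NULL  # forecasts go to CSV, not the JSON report
    r
  })
  as.character(jsonlite::toJSON(stripped, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

#' Generate the synthetic benchmark sequences
#'
#' Emulates the long-range compositional heterogeneity (isochore-like
#' domains) of real genomes: the sequence is built from consecutive
#' `block_len`-base blocks, each drawn i.i.d. from base probabilities that
#' drift slowly across blocks. Two independent latent AR(1) paths (lag-1
#' coefficient `latent_ar`, stationary sd `skew_sd`) modulate the A-vs-T
#' and G-vs-C skews around the uniform composition. Windowed encodings of
#' such sequences carry smooth, small-amplitude, forecastable structure on
#' top of the binomial window noise — the regime in which one-step
#' forecasting is meaningful.
#'
#' @param n_seqs Number of sequences.
#' @param length Bases per sequence.
#' @param block_len Bases per constant-composition block.
#' @param skew_sd Stationary sd of each latent skew path.
#' @param latent_ar AR(1) coefficient of the latent paths across blocks.
#' @param seed Master seed.
#' @return List of [dna_seq] objects.
#' @export
synthetic_benchmark <- function(n_seqs = 6L, length = 6000L, block_len = 300L,
                                skew_sd = 0.05, latent_ar = 0.9, seed = 1L) {
  lapply(seq_len(n_seqs), function(i) {
    n_blocks <- ceiling(length / block_len)
    sseed <- derive_seed(seed, 1000L + i)
    skews <- with_seed(sseed, {
      innov_sd <- skew_sd * sqrt(1 - latent_ar^2)
      replicate(2L, {
        s <- numeric(n_blocks)
        s[1] <- stats::rnorm(1L, sd = skew_sd)
        if (n_blocks > 1L) for (b in 2:n_blocks) {
          s[b] <- latent_ar * s[b - 1L] + stats::rnorm(1L, sd = innov_sd)
        }
        pmin(pmax(s, -0.18), 0.18)
      })
    })
    chunks <- vapply(seq_len(n_blocks), function(b) {
      at <- skews[b, 1L]; gc <- skews[b, 2L]
      probs <- c(0.25 + at, 0.25 + gc, 0.25 - gc, 0.25 - at)  # A C G T
      len_b <- min(block_len, length - (b - 1L) * block_len)
      generate_dna(len_b, model = "uniform", base_probs = probs,
                   seed = derive_seed(sseed, b))$bases
    }, character(1))
    dna_seq(sprintf("synth%02d", i), paste(chunks, collapse = ""))
  })
}
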