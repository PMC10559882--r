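test_that("weighted_fuse is an elementwise convex combination", {
  expect_equal(weighted_fuse(c(2), c(4), ensemble_weights(0.5, 0.5)), 3)
  o1 <- stats::rnorm(10); o2 <- stats::rnorm(10)
  expect_equal(weighted_fuse(o1, o2, ensemble_weights(1, 0)), o1)
  expect_equal(weighted_fuse(o1, o2, ensemble_weights(0, 1)), o2)
  wv <- stats::runif(10)
  expect_equal(weighted_fuse(o1, o2, ensemble_weights(wv, 1 - wv)),
               wv * o1 + (1 - wv) * o2)
  expect_error(weighted_fuse(o1, o2[1:5], ensemble_weights(0.5, 0.5)),
               "lengths differ")
  expect_error(ensemble_weights(-0.1, 1.1), "0, 1")
  expect_error(ensemble_weights(0.4, 0.4), "sum to 1")
})

test_that("learn_weights recovers the optimal convex weight on the grid", {
  y <- stats::rnorm(60, mean = 5)
  w1 <- learn_weights(y, y + stats::rnorm(60, sd = 2), y)
  expect_equal(w1$w_ar, 1)
  # symmetric biases cancel at w = 0.5
  w2 <- learn_weights(y + 1, y - 1, y)
  expect_equal(w2$w_ar, 0.5)
  # fused MSE never worse than either component beyond the grid tolerance
  o_ar <- y + stats::rnorm(60, sd = 0.5); o_lstm <- y + stats::rnorm(60, sd = 1)
  w3 <- learn_weights(o_ar, o_lstm, y)
  fused <- weighted_fuse(o_ar, o_lstm, w3)
  comp <- min(mean((o_ar - y)^2), mean((o_lstm - y)^2))
  expect_lte(mean((fused - y)^2), comp + 1e-10)
  expect_warning(w4 <- learn_weights(o_ar, o_ar, y), "identical")
  expect_equal(w4$w_ar, 0.5)
})

test_that("ablation switches map to the documented model variant names", {
  expect_equal(model_variant_name(pipeline_config()), "SaPt-CNN-LSTM-AR-EA")
  expect_equal(model_variant_name(pipeline_config(use_sapt = FALSE)),
               "CNN-LSTM-AR-EA")
  expect_equal(model_variant_name(pipeline_config(use_conv = FALSE)),
               "SaPt-LSTM-AR-EA")
  expect_equal(model_variant_name(pipeline_config(use_ar = FALSE)),
               "SaPt-CNN-LSTM-EA")
  expect_equal(model_variant_name(pipeline_config(use_tuning = FALSE)),
               "SaPt-CNN-LSTM-AR")
})

test_that("synthetic benchmark sequences are reproducible and well-formed", {
  a <- synthetic_benchmark(n_seqs = 2, length = 1500, seed = 3)
  b <- synthetic_benchmark(n_seqs = 2, length = 1500, seed = 3)
  expect_identical(lapply(a, `[[`, "bases"), lapply(b, `[[`, "bases"))
  expect_equal(vapply(a, `[[`, 0L, "n"), c(1500L, 1500L))
  expect_false(identical(a[[1]]$bases, a[[2]]$bases))
  expect_true(all(grepl("^[ACGT]+$", vapply(a, `[[`, "", "bases"))))
})

quick_config <- function(seed = 1L) {
  pipeline_config(
    arfima_pso = pso_control(swarm_size = 4L, iterations = 2L),
    cnn_pso = pso_control(swarm_size = 3L, iterations = 2L),
    cnn_spec = cnn_lstm_spec(n_tr = 15L, n_hn = 6L, d_tr = 0.02,
                             n_kernels = 4L),
    n_tr_range = c(10, 25), n_hn_range = c(4, 8),
    p_max = 2L, q_max = 2L, sapt_patience = 1L, sapt_max_epochs = 5L,
    seed = seed
  )
}

test_that("the end-to-end pipeline produces finite, structured reports", {
  seqs <- synthetic_benchmark(n_seqs = 1, length = 4800, seed = 21)
  rep <- suppressWarnings(run_pipeline(seqs, quick_config(seed = 2)))
  expect_s3_class(rep, "pipeline_report")
  expect_equal(rep$model, "SaPt-CNN-LSTM-AR-EA")
  r <- rep$sequences[[1]]
  expect_null(r$error)
  expect_equal(r$n_points, 80L)
  expect_equal(unlist(r$splits), c(train = 56L, validation = 12L, test = 12L))
  for (split in c("train", "validation", "test")) {
    expect_true(is.finite(r$metrics[[split]]$mape))
    expect_true(is.finite(r$metrics[[split]]$r2))
    expect_true(is.finite(r$metrics[[split]]$var))
  }
  expect_length(r$arfima$orders, 6L)
  expect_equal(sum(unlist(r$arfima$channel_weights)), 1, tolerance = 1e-10)
  expect_true(r$fusion$w_ar >= 0 && r$fusion$w_ar <= 1)
  expect_true(is.finite(r$baselines$naive$mape))
  expect_true(is.finite(r$dm_vs_naive$statistic))
})

test_that("a failing sequence is isolated and the rest complete", {
  seqs <- c(synthetic_benchmark(n_seqs = 1, length = 4800, seed = 22),
            list(dna_seq("tiny", "ACGTACGT")))
  rep <- suppressWarnings(run_pipeline(seqs, quick_config(seed = 3)))
  expect_null(rep$sequences[[1]]$error)
  expect_false(is.null(rep$sequences$tiny$error))
})

test_that("pipeline reports are byte-identical under a fixed seed", {
  seqs <- synthetic_benchmark(n_seqs = 1, length = 4800, seed = 23)
  r1 <- suppressWarnings(run_pipeline(seqs, quick_config(seed = 4)))
  r2 <- suppressWarnings(run_pipeline(seqs, quick_config(seed = 4)))
  expect_identical(report_to_json(r1), report_to_json(r2))
})

test_that("ablation variants run end to end and are flagged in the report", {
  seqs <- synthetic_benchmark(n_seqs = 1, length = 4800, seed = 24)
  cfg <- quick_config(seed = 5); cfg$use_ar <- FALSE
  rep <- suppressWarnings(run_pipeline(seqs, cfg))
  expect_equal(rep$model, "SaPt-CNN-LSTM-EA")
  r <- rep$sequences[[1]]
  expect_null(r$error)
  expect_null(r$arfima)
  expect_equal(r$fusion$w_ar, 0)
  expect_true(is.finite(r$metrics$test$mape))
})

test_that("reports and forecasts are written to disk on request", {
  seqs <- synthetic_benchmark(n_seqs = 1, length = 4800, seed = 25)
  out <- withr::local_tempdir()
  rep <- suppressWarnings(run_pipeline(seqs, quick_config(seed = 6),
                                       out_dir = out))
  expect_true(file.exists(file.path(out, "report.json")))
  parsed <- jsonlite::fromJSON(file.path(out, "report.json"))
  expect_equal(parsed$model, "SaPt-CNN-LSTM-AR-EA")
  csvs <- list.files(out, pattern = "_forecasts.csv$")
  expect_length(csvs, 1L)
  fc <- utils::read.csv(file.path(out, csvs[1]))
  expect_named(fc, c("index", "split", "observed", "fused", "o_ar", "o_lstm"))
})
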