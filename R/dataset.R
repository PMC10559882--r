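#' Window a series into data points
#'
#' Consecutive non-overlapping windows of `window_len` values; each complete
#' window is reduced to one data point by `aggregate`. A trailing incomplete
#' window is discarded, so the number of points is floor(n / window_len).
#' The default window of 60 bases with mean aggregation maps each source
#' sequence length L to floor(L / 60) data points.
#'
#' @param series A one-channel [bts] or numeric vector.
#' @param window_len Window length in values (>= 1).
#' @param aggregate `"mean"` or `"first"`.
#' @return A [bts] of data points (or numeric vector if the input was one).
#' @export
window_series <- function(series, window_len = 60L,
                          aggregate = c("mean", "first")) {
  aggregate <- match.arg(aggregate)
  if (!is.numeric(window_len) || window_len < 1) {
    stop_arg("`window_len` must be >= 1")
  }
  window_len <- as.integer(window_len)
  is_bts <- inherits(series, "bts")
  x <- if (is_bts) series$values else series
  if (is.matrix(x)) stop_arg("window_series expects a one-channel series")
  m <- length(x) %/% window_len
  if (m == 0L) warning("series shorter than one window; 0 data points")
  x <- x[seq_len(m * window_len)]
  pts <- if (m == 0L) numeric(0) else {
    mat <- matrix(x, nrow = window_len)
    if (aggregate == "mean") colMeans(mat) else mat[1L, ]
  }
  if (is_bts) bts(pts, series$encoding, series$source_id, series$normalization)
  else pts
}

#' Chronological train/validation/test split
#'
#' Contiguous split with validation = test = floor(0.15 * n) points and the
#' remainder (roughly 70%) to training, training first, then validation,
#' then test.
#'
#' @param points Numeric vector (or one-channel [bts]) of data points.
#' @param f_val,f_test Validation and test fractions.
#' @return An object of class `data_split`: list with `train`, `validation`,
#'   `test` numeric vectors and `sizes`.
#' @examples
#' split_series(seq_len(100))$sizes  # 70 15 15
#' @export
split_series <- function(points, f_val = 0.15, f_test = 0.15) {
  x <- if (inherits(points, "bts")) points$values else points
  check_numeric_vector(x, "points", min_len = 0L)
  n <- length(x)
  if (n < 3L) stop_arg("need at least 3 points to split (got %d)", n)
  n_val <- floor(f_val * n)
  n_test <- floor(f_test * n)
  n_train <- n - n_val - n_test
  structure(list(
    train = x[seq_len(n_train)],
    validation = x[n_train + seq_len(n_val)],
    test = x[n_train + n_val + seq_len(n_test)],
    sizes = c(train = n_train, validation = n_val, test = n_test)
  ), class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> train=%d validation=%d test=%d\n",
              x$sizes[1], x$sizes[2], x$sizes[3]))
  invisible(x)
}

#' Normalize a series (min-max or variance)
#'
#' `"minmax"` maps onto \[0, 1\] by (x - min) / (max - min); `"variance"`
#' standardizes by (x - mean) / sd (sample sd). The statistics are recorded
#' so the transform can be inverted, and should be fitted on the training
#' segment only (pass it via `fit_on`) to avoid leakage into validation/test.
#'
#' @param series Numeric vector or one-channel [bts].
#' @param mode `"minmax"` or `"variance"`.
#' @param fit_on Optional numeric vector whose statistics are used (default:
#'   the series itself).
#' @return List with `values` (normalized series, same container as input)
#'   and `params` (a `norm_params` object).
#' @export
normalize_series <- function(series, mode = c("minmax", "variance"),
                             fit_on = NULL) {
  mode <- match.arg(mode)
  is_bts <- inherits(series, "bts")
  x <- if (is_bts) series$values else series
  check_numeric_vector(x, "series")
  ref <- if (is.null(fit_on)) x else check_numeric_vector(fit_on, "fit_on")
  if (mode == "minmax") {
    lo <- min(ref); hi <- max(ref)
    if (hi - lo < .Machine$double.eps) {
      stop_arg("degenerate series: max equals min, cannot min-max normalize")
    }
    params <- structure(list(mode = "minmax", min = lo, max = hi),
                        class = "norm_params")
    v <- (x - lo) / (hi - lo)
  } else {
    mu <- mean(ref); s <- stats::sd(ref)
    if (!is.finite(s) || s < .Machine$double.eps) {
      stop_arg("degenerate series: zero standard deviation")
    }
    params <- structure(list(mode = "variance", mean = mu, sd = s),
                        class = "norm_params")
    v <- (x - mu) / s
  }
  values <- if (is_bts) {
    bts(v, series$encoding, series$source_id, normalization = mode)
  } else v
  list(values = values, params = params)
}

#' Invert a normalization
#' @param series Normalized numeric vector or [bts].
#' @param params `norm_params` returned by [normalize_series()].
#' @return Series in original units (same container as input).
#' @export
inverse_normalize <- function(series, params) {
  stopifnot(inherits(params, "norm_params"))
  is_bts <- inherits(series, "bts")
  x <- if (is_bts) series$values else series
  v <- if (params$mode == "minmax") {
    x * (params$max - params$min) + params$min
  } else {
    x * params$sd + params$mean
  }
  if (is_bts) bts(v, series$encoding, series$source_id, "none") else v
}

#' Derive the six standard series of a DNA sequence
#'
#' Encodes the sequence three ways (spectral, CGR scalar, Z-curve), windows
#' each identically, and returns each windowed encoding under both
#' normalizations: \{spectral, cgr, z\} x \{minmax, variance\}.
#' Normalization statistics are fitted on the training segment of the
#' chronological split (leakage-safe) and returned for inversion.
#'
#' @param seq A [dna_seq] or character string.
#' @param window_len Window length in bases.
#' @param aggregate Window aggregation mode.
#' @param cgr_mode Scalar projection for CGR (see [cgr_scalar()]).
#' @param f_val,f_test Split fractions used to locate the training segment.
#' @return List with `series` (named list of 6 normalized [bts]), `params`
#'   (matching `norm_params`), `raw` (the 3 windowed un-normalized series)
#'   and `split_sizes`.
#' @export
derive_six_series <- function(seq, window_len = 60L, aggregate = "mean",
                              cgr_mode = "norm", f_val = 0.15, f_test = 0.15) {
  enc <- list(
    spectral = window_series(encode_spectral(seq), window_len, aggregate),
    cgr = window_series(cgr_scalar(encode_cgr(seq), cgr_mode), window_len,
                        aggregate),
    z = window_series(encode_z(seq), window_len, aggregate)
  )
  npts <- length(enc$spectral$values)
  if (npts < 3L) stop_arg("sequence too short: only %d data points", npts)
  sizes <- split_series(seq_len(npts), f_val, f_test)$sizes
  train_idx <- seq_len(sizes[["train"]])
  series <- list(); params <- list()
  for (e in names(enc)) {
    for (m in c("minmax", "variance")) {
      key <- paste(e, m, sep = "_")
      nm <- normalize_series(enc[[e]], m,
                             fit_on = enc[[e]]$values[train_idx])
      series[[key]] <- nm$values
      params[[key]] <- nm$params
    }
  }
  list(series = series, params = params, raw = enc, split_sizes = sizes)
}

#' Build a supervised lookback set from aligned channels
#'
#' Sample j takes the `lookback` consecutive rows starting at j of every
#' channel as input and the target channel's value immediately after the
#' block as target; there are L - lookback samples for channels of length L.
#'
#' @param channels Numeric matrix (L x N, one column per channel) or list of
#'   equal-length vectors / one-channel [bts] objects.
#' @param lookback Window length T (>= 1).
#' @param target Column index (or name) of the target channel.
#' @return An object of class `supervised_set`: list with `inputs` (array
#'   T x N x S), `targets` (length S), `lookback`, `n_channels`, `target`.
#' @export
make_supervised <- function(channels, lookback = 8L, target = 1L) {
  if (is.list(channels) && !is.matrix(channels)) {
    vecs <- lapply(channels,
                   function(ch) if (inherits(ch, "bts")) ch$values else ch)
    if (length(unique(lengths(vecs))) != 1L) {
      stop_arg("all channels must have equal length")
    }
    channels <- do.call(cbind, vecs)
  }
  channels <- as.matrix(channels)
  L <- nrow(channels); N <- ncol(channels)
  if (!is.numeric(lookback) || lookback < 1) stop_arg("`lookback` must be >= 1")
  lookback <- as.integer(lookback)
  if (L <= lookback) {
    stop_arg("need more than lookback=%d points (got %d)", lookback, L)
  }
  if (is.character(target)) target <- match(target, colnames(channels))
  if (is.na(target) || target < 1 || target > N) {
    stop_arg("invalid target channel")
  }
  S <- L - lookback
  inputs <- array(0, dim = c(lookback, N, S))
  for (j in seq_len(S)) {
    inputs[, , j] <- channels[j:(j + lookback - 1L), , drop = FALSE]
  }
  structure(list(inputs = inputs, targets = channels[lookback + seq_len(S),
                                                     target],
                 lookback = lookback, n_channels = N, target = target,
                 n_samples = S), class = "supervised_set")
}

#' Rolling mean / standard deviation stationarity summary
#'
#' Plain-numbers substitute for visual stationarity inspection: rolling mean
#' and sd over a moving window, plus their drift (first-to-last-quarter
#' change) as a quick non-stationarity indicator.
#'
#' @param x Numeric vector.
#' @param window Rolling window length.
#' @return Data frame with columns `index`, `roll_mean`, `roll_sd`, and
#'   attributes `mean_drift`, `sd_drift`.
#' @export
stationarity_summary <- function(x, window = 20L) {
  x <- if (inherits(x, "bts")) x$values else x
  check_numeric_vector(x, "x", min_len = 2L)
  window <- min(as.integer(window), length(x))
  n <- length(x) - window + 1L
  rm_ <- vapply(seq_len(n), function(i) mean(x[i:(i + window - 1L)]), 0)
  rs_ <- vapply(seq_len(n), function(i) stats::sd(x[i:(i + window - 1L)]), 0)
  out <- data.frame(index = seq_len(n), roll_mean = rm_, roll_sd = rs_)
  q <- max(1L, n %/% 4L)
  attr(out, "mean_drift") <- mean(rm_[(n - q + 1L):n]) - mean(rm_[1:q])
  attr(out, "sd_drift") <- mean(rs_[(n - q + 1L):n]) - mean(rs_[1:q])
  out
}
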