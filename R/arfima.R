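#' Fractional differencing weights
#'
#' Binomial-expansion coefficients of the fractional difference operator
#' (1 - B)^d: c_0 = 1, c_k = c_(k-1) * (k - 1 - d) / k. For integer d these
#' terminate (d = 1 gives 1, -1, 0, ...); for fractional d they decay
#' hyperbolically, which is what produces long memory.
#'
#' @param d Differencing order.
#' @param K Truncation lag (>= 0).
#' @return Numeric vector c_0 .. c_K of length K + 1.
#' @examples
#' fracdiff_weights(0.5, 3)  # 1 -0.5 -0.125 -0.0625
#' @export
fracdiff_weights <- function(d, K) {
  stopifnot(is.numeric(d), length(d) == 1L, K >= 0)
  K <- as.integer(K)
  w <- numeric(K + 1L)
  w[1] <- 1
  if (K > 0L) for (k in seq_len(K)) w[k + 1L] <- w[k] * (k - 1 - d) / k
  w
}

# Truncated causal convolution: y_t = sum_{k=0}^{t-1} w_{k} x_{t-k},
# FFT-based via polynomial multiplication.
conv_trunc <- function(x, w) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (length(w) == 1L) return(w * x)
  full <- stats::convolve(x, rev(w), type = "open")
  full[seq_len(n)]
}

#' Fractionally difference a series
#'
#' Applies (1 - B)^d by truncated convolution with [fracdiff_weights()],
#' truncation being the full available history (exact, no fixed-lag cutoff).
#' For positive integer d the first d values have no complete history and
#' are dropped (d = 1 reduces to the ordinary first difference); they are
#' kept as the `history` attribute so [frac_integrate()] can invert exactly.
#'
#' @param x Numeric series.
#' @param d Differencing order.
#' @return Differenced series with attributes `d` and `history`.
#' @export
frac_difference <- function(x, d) {
  check_numeric_vector(x, "x")
  n <- length(x)
  n_drop <- if (d >= 1 && abs(d - round(d)) < 1e-12) as.integer(round(d)) else 0L
  w <- conv_trunc(x, fracdiff_weights(d, n - 1L))
  out <- if (n_drop > 0L) w[-seq_len(min(n_drop, n))] else w
  attr(out, "d") <- d
  attr(out, "history") <- if (n_drop > 0L) x[seq_len(min(n_drop, n))] else numeric(0)
  out
}

#' Fractionally integrate a series
#'
#' Exact inverse of [frac_difference()]: given the same `history` (the
#' values dropped for integer d; empty otherwise), reconstructs the original
#' series. Without history the inverse operator (1 - B)^(-d) is applied by
#' truncated convolution.
#'
#' @param w Differenced series.
#' @param d Differencing order used to produce it.
#' @param history Values dropped by [frac_difference()] (integer d only).
#' @return The reconstructed series, including `history` at the front.
#' @export
frac_integrate <- function(w, d, history = NULL) {
  check_numeric_vector(w, "w", min_len = 0L)
  if (is.null(history)) history <- attr(w, "history")
  if (is.null(history)) history <- numeric(0)
  h <- length(history)
  m <- length(w)
  if (m == 0L) return(as.numeric(history))
  if (h == 0L) {
    return(conv_trunc(as.numeric(w), fracdiff_weights(-d, m - 1L)))
  }
  # sequential inversion of w_t = sum_k c_k x_{t-k} with known leading values
  cw <- fracdiff_weights(d, h + m - 1L)
  x <- c(as.numeric(history), numeric(m))
  for (t in seq_len(m)) {
    pos <- h + t
    lags <- seq_len(pos - 1L)
    x[pos] <- w[t] - sum(cw[lags + 1L] * x[pos - lags])
  }
  x
}

#' Fit an ARFIMA(p, d, q) model at fixed orders
#'
#' The series is fractionally differenced by `d` (full-history truncation)
#' and an ARMA(p, q) with mean is estimated on the result by conditional
#' sum of squares (`stats::arima`, method "CSS"). `d` itself is treated as
#' a searched parameter (see [tune_arfima()]), not jointly MLE-estimated.
#'
#' @param x Training series.
#' @param p,q AR and MA orders (integers >= 0).
#' @param d Fractional differencing order.
#' @return Object of class `arfima_fit`: orders, coefficients `ar`, `ma`,
#'   `mean`, innovation variance `sigma2`, the CSS value, and the training
#'   series.
#' @export
fit_arfima <- function(x, p = 0L, d = 0, q = 0L) {
  check_numeric_vector(x, "x")
  p <- as.integer(p); q <- as.integer(q)
  if (p < 0L || q < 0L) stop_arg("orders must be >= 0")
  if (length(x) <= 10 * (p + q + 1)) {
    stop_arg("training series too short for orders (%d, %d): need > %d points",
             p, q, 10 * (p + q + 1))
  }
  w <- as.numeric(frac_difference(x, d))
  hist0 <- attr(frac_difference(x, d), "history")
  if (stats::sd(w) < 1e-12) {
    # degenerate (constant after differencing): pure mean model
    fitted <- list(ar = rep(0, p), ma = rep(0, q), mean = mean(w),
                   sigma2 = 0, css = 0)
  } else if (p == 0L && q == 0L) {
    mu <- mean(w)
    fitted <- list(ar = numeric(0), ma = numeric(0), mean = mu,
                   sigma2 = mean((w - mu)^2), css = sum((w - mu)^2))
  } else {
    fit <- tryCatch(
      suppressWarnings(stats::arima(w, order = c(p, 0L, q), method = "CSS",
                                    include.mean = TRUE)),
      error = function(e) stop_arg("ARFIMA(%d, %g, %d) CSS fit failed: %s",
                                   p, d, q, conditionMessage(e))
    )
    cf <- stats::coef(fit)
    ar <- if (p > 0L) unname(cf[paste0("ar", seq_len(p))]) else numeric(0)
    ma <- if (q > 0L) unname(cf[paste0("ma", seq_len(q))]) else numeric(0)
    fitted <- list(ar = ar, ma = ma,
                   mean = if ("intercept" %in% names(cf))
                     unname(cf["intercept"]) else 0,
                   sigma2 = fit$sigma2,
                   css = sum(stats::residuals(fit)^2, na.rm = TRUE))
    if (p > 0L && any(Mod(polyroot(c(1, -ar))) <= 1 + 1e-8)) {
      warning(sprintf("fitted AR polynomial of ARFIMA(%d, %g, %d) is not stationary",
                      p, d, q))
    }
  }
  structure(list(p = p, d = d, q = q, ar = fitted$ar, ma = fitted$ma,
                 mean = fitted$mean, sigma2 = fitted$sigma2,
                 css = fitted$css, train = as.numeric(x),
                 diff_history = hist0), class = "arfima_fit")
}

#' @export
print.arfima_fit <- function(x, ...) {
  cat(sprintf("<arfima_fit> ARFIMA(%d, %g, %d) mean=%.4g sigma2=%.4g\n",
              x$p, x$d, x$q, x$mean, x$sigma2))
  if (x$p > 0) cat("  ar:", paste(sprintf("%.4f", x$ar), collapse = " "), "\n")
  if (x$q > 0) cat("  ma:", paste(sprintf("%.4f", x$ma), collapse = " "), "\n")
  invisible(x)
}

# ARMA innovation recursion on a differenced series: returns one-step
# predictions and innovations, with pre-sample values at the mean.
arma_innovations <- function(w, ar, ma, mu) {
  n <- length(w)
  p <- length(ar); q <- length(ma)
  e <- numeric(n); pred <- numeric(n)
  wc <- w - mu
  for (t in seq_len(n)) {
    acc <- 0
    if (p > 0L) for (i in seq_len(min(p, t - 1L))) acc <- acc + ar[i] * wc[t - i]
    if (q > 0L) for (j in seq_len(min(q, t - 1L))) acc <- acc + ma[j] * e[t - j]
    pred[t] <- mu + acc
    e[t] <- w[t] - pred[t]
  }
  list(pred = pred, innov = e)
}

#' Iterated multi-step ARFIMA forecasts
#'
#' One-step forecasts are iterated in the differenced domain (future
#' innovations set to zero) and re-integrated back to data units through
#' the fractional filter.
#'
#' @param fit An `arfima_fit`.
#' @param history Series to forecast from (default: the training series).
#' @param h Forecast horizon (>= 1).
#' @return Numeric vector of `h` forecasts.
#' @export
forecast_arfima <- function(fit, history = NULL, h = 1L) {
  stopifnot(inherits(fit, "arfima_fit"))
  if (h < 1L) stop_arg("`h` must be >= 1")
  h <- as.integer(h)
  x <- if (is.null(history)) fit$train else check_numeric_vector(history, "history")
  n <- length(x)
  xx <- c(x, numeric(h))
  for (j in seq_len(h)) {
    m <- n + j
    wd <- as.numeric(frac_difference(xx[seq_len(m - 1L)], fit$d))
    # innovations up to m-1, then forecast the next differenced value
    rec <- arma_innovations(wd, fit$ar, fit$ma, fit$mean)
    p <- fit$p; q <- fit$q
    acc <- 0
    nw <- length(wd)
    if (p > 0L) for (i in seq_len(min(p, nw)))
      acc <- acc + fit$ar[i] * (wd[nw - i + 1L] - fit$mean)
    if (q > 0L) for (k in seq_len(min(q, nw)))
      acc <- acc + fit$ma[k] * rec$innov[nw - k + 1L]
    w_next <- fit$mean + acc
    # invert the fractional filter for the new point:
    # w_t = x_t + sum_{k>=1} c_k x_{t-k}
    cw <- fracdiff_weights(fit$d, m - 1L)
    tail_sum <- if (m > 1L) sum(cw[2:m] * xx[(m - 1L):1L]) else 0
    xx[m] <- w_next - tail_sum
  }
  xx[n + seq_len(h)]
}

#' Rolling one-step ARFIMA forecasts over a held-out segment
#'
#' Refit-free filter-update evaluation: the fitted coefficients are held
#' fixed, the fractional filter and ARMA innovation recursion are run over
#' the concatenated history + evaluation series, and the one-step prediction
#' for each evaluation point uses only data before it.
#'
#' @param fit An `arfima_fit`.
#' @param newdata Evaluation series that chronologically follows the data in
#'   `history`.
#' @param history Series preceding `newdata` (default: training series).
#' @return One-step forecasts aligned with `newdata`.
#' @export
rolling_forecast_arfima <- function(fit, newdata, history = NULL) {
  stopifnot(inherits(fit, "arfima_fit"))
  check_numeric_vector(newdata, "newdata")
  x <- if (is.null(history)) fit$train else check_numeric_vector(history, "history")
  full <- c(x, newdata)
  wd <- frac_difference(full, fit$d)
  rec <- arma_innovations(as.numeric(wd), fit$ar, fit$ma, fit$mean)
  n_drop <- length(attr(wd, "history"))
  # one-step error in data units equals the innovation in the differenced
  # domain: xhat_t = x_t - e_t
  innov_full <- c(numeric(n_drop), rec$innov)  # align to `full`
  idx <- length(x) + seq_along(newdata)
  full[idx] - innov_full[idx]
}

#' PSO search of ARFIMA orders
#'
#' Particle-swarm search over p in \[0, 5\] (integer), d in
#' \[-0.49, 0.49\], q in \[0, 5\] (integer). Fitness of a candidate is the
#' MAPE of its rolling one-step forecasts on the validation segment (fit on
#' the training segment only); if the validation series contains zeros the
#' root mean squared error is used instead. The (0, 0, 0) baseline is
#' seeded as one particle, so the tuned model never validates worse than
#' the white-noise-with-mean baseline.
#'
#' @param train,val Training and validation series (chronological).
#' @param p_max,q_max Upper bounds of the integer order search.
#' @param d_range Search interval for d.
#' @param control A [pso_control()].
#' @return List with `fit` (refitted best `arfima_fit`), `orders`,
#'   `val_fitness`, `history`.
#' @export
tune_arfima <- function(train, val, p_max = 5L, q_max = 5L,
                        d_range = c(-0.49, 0.49), control = pso_control()) {
  check_numeric_vector(train, "train"); check_numeric_vector(val, "val")
  use_mape <- all(val != 0)
  objective <- function(pos) {
    p <- as.integer(round(pos[1])); d <- pos[2]; q <- as.integer(round(pos[3]))
    f <- fit_arfima(train, p, d, q)
    pred <- rolling_forecast_arfima(f, val, history = train)
    if (use_mape) mape(val, pred) else sqrt(mean((val - pred)^2))
  }
  res <- pso_optimize(objective, lower = c(0, d_range[1], 0),
                      upper = c(p_max, d_range[2], q_max),
                      integer_mask = c(TRUE, FALSE, TRUE),
                      control = control, incumbent = c(0, 0, 0))
  orders <- list(p = as.integer(res$position[1]), d = res$position[2],
                 q = as.integer(res$position[3]))
  list(fit = fit_arfima(train, orders$p, orders$d, orders$q),
       orders = orders, val_fitness = res$fitness, history = res$history)
}

#' Serialize a fitted ARFIMA model to JSON
#' @param fit An `arfima_fit`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
arfima_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "arfima_fit"))
  doc <- jsonlite::toJSON(fit[c("p", "d", "q", "ar", "ma", "mean", "sigma2",
                                "css")], auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
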