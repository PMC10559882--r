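#' Mean absolute percentage error
#'
#' MAPE = (1/N) * sum |(y_i - yhat_i) / y_i| * 100, in percent. A zero true
#' value makes the ratio undefined; the function raises rather than silently
#' dropping points (silent exclusion changes N and corrupts comparisons).
#' Encoded series are bounded away from 0 by construction (spectral lies in
#' \[1, 4\]), so this does not bite in the pipeline.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return MAPE in percent.
#' @examples
#' mape(c(100), c(90))  # 10
#' @export
mape <- function(y, yhat) {
  check_numeric_vector(y, "y"); check_numeric_vector(yhat, "yhat")
  if (length(y) != length(yhat)) stop_arg("`y` and `yhat` lengths differ")
  zero <- which(y == 0)
  if (length(zero) > 0L) {
    stop_arg("y contains zero at position %d: MAPE undefined", zero[1])
  }
  mean(abs((y - yhat) / y)) * 100
}

#' Squared correlation between observed and predicted values
#'
#' The ratio of the squared covariance to the product of the sums of
#' squares — the square of the Pearson correlation. Affine-invariant and
#' symmetric in its arguments; note it is not the regression coefficient of
#' determination.
#'
#' @param y Observed values (non-constant).
#' @param yhat Predicted values (non-constant).
#' @return Value in \[0, 1\].
#' @export
r_squared <- function(y, yhat) {
  check_numeric_vector(y, "y", 2L); check_numeric_vector(yhat, "yhat", 2L)
  if (length(y) != length(yhat)) stop_arg("`y` and `yhat` lengths differ")
  dy <- y - mean(y); dp <- yhat - mean(yhat)
  ssy <- sum(dy^2); ssp <- sum(dp^2)
  if (ssy < .Machine$double.eps || ssp < .Machine$double.eps) {
    stop_arg("constant input: squared correlation undefined")
  }
  sum(dy * dp)^2 / (ssy * ssp)
}

#' Accuracy growth rate between two models' MAPEs
#'
#' P_MAPE = |MAPE_i - MAPE_j| / MAPE_i * 100: the relative accuracy change
#' of model j against reference model i, in percent.
#'
#' @param mape_i Reference model MAPE (> 0).
#' @param mape_j Comparison model MAPE.
#' @return Percent growth rate.
#' @export
accuracy_growth <- function(mape_i, mape_j) {
  stopifnot(is.numeric(mape_i), is.numeric(mape_j))
  if (mape_i == 0) stop_arg("reference MAPE is zero: growth rate undefined")
  abs(mape_i - mape_j) / mape_i * 100
}

#' Diebold-Mariano test for equal predictive accuracy
#'
#' Given two forecast-error series, forms the loss differential d_t (squared
#' or absolute loss) and computes DM = mean(d) / sqrt(V / N), where V is the
#' rectangular-kernel HAC estimate of the long-run variance of d with h - 1
#' lags (h the forecast horizon). |DM| is compared with the standard-normal
#' two-sided critical values 1.645 (90%), 1.96 (95%) and 2.58 (99%).
#' A Harvey small-sample correction is available but off by default.
#'
#' @param errors_1,errors_2 Forecast-error series of the two models.
#' @param loss `"squared"` or `"absolute"`.
#' @param h Forecast horizon (>= 1); the HAC variance uses h - 1 lags.
#' @param harvey Apply the Harvey-Leybourne-Newbold correction.
#' @return List with `statistic`, `critical` (named 90/95/99 thresholds),
#'   `reject` (named logical vector), `n`.
#' @export
dm_test <- function(errors_1, errors_2, loss = c("squared", "absolute"),
                    h = 1L, harvey = FALSE) {
  loss <- match.arg(loss)
  check_numeric_vector(errors_1, "errors_1")
  check_numeric_vector(errors_2, "errors_2")
  if (length(errors_1) != length(errors_2)) {
    stop_arg("error series lengths differ")
  }
  n <- length(errors_1)
  if (n < 10L) stop_arg("need at least 10 forecasts for the DM test (got %d)", n)
  if (h < 1L) stop_arg("`h` must be >= 1")
  d <- if (loss == "squared") errors_1^2 - errors_2^2 else abs(errors_1) - abs(errors_2)
  dbar <- mean(d)
  dc <- d - dbar
  # rectangular HAC: gamma_0 + 2 * sum_{k=1}^{h-1} gamma_k
  v <- sum(dc^2) / n
  if (h > 1L) {
    for (k in seq_len(h - 1L)) {
      v <- v + 2 * sum(dc[(k + 1):n] * dc[1:(n - k)]) / n
    }
  }
  if (v <= 0) {
    stat <- if (abs(dbar) < .Machine$double.eps) 0 else sign(dbar) * Inf
  } else {
    stat <- dbar / sqrt(v / n)
    if (harvey) {
      stat <- stat * sqrt((n + 1 - 2 * h + h * (h - 1) / n) / n)
    }
  }
  critical <- c(`90` = 1.645, `95` = 1.96, `99` = 2.58)
  list(statistic = stat, critical = critical,
       reject = abs(stat) > critical, n = n)
}

#' Variance of forecast residuals (stability indicator)
#'
#' The square of the sample standard deviation of the residuals yhat - y.
#' A constant bias contributes nothing; only the spread of the residuals
#' does. Lower values indicate a more stable model.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @param ddof Degrees-of-freedom correction (1 = sample convention).
#' @return Residual variance in squared data units.
#' @export
var_residuals <- function(y, yhat, ddof = 1L) {
  check_numeric_vector(y, "y", 2L); check_numeric_vector(yhat, "yhat", 2L)
  if (length(y) != length(yhat)) stop_arg("`y` and `yhat` lengths differ")
  r <- yhat - y
  sum((r - mean(r))^2) / (length(r) - ddof)
}

#' Full evaluation report for one forecast series
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return List with `n`, `mape`, `r2`, `var`.
#' @export
eval_report <- function(y, yhat) {
  r2 <- tryCatch(r_squared(y, yhat), error = function(e) {
    warning("squared correlation undefined (constant input); reporting 0")
    0
  })
  list(n = length(y), mape = mape(y, yhat), r2 = r2,
       var = var_residuals(y, yhat))
}
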