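#' Regression-predicted next trend value
#'
#' The reference forecast against which prediction error is scored. For
#' consistent trends this is the generating equation evaluated one month
#' past the series (`intercept + slope * (length + 1)`). For inconsistent
#' trends, whose appended 49th point breaks the trend, an ordinary
#' least-squares line is refitted to all 49 presented points and evaluated
#' at month 50.
#'
#' @param spec The [trend_spec()] the series was generated from.
#' @param series The presented `salary_series` (or numeric vector); its
#'   length must match `spec$length`.
#' @return The predicted next trend value in pounds.
#' @examples
#' pos <- trend_spec("positive", "consistent", noise_variance = 0)
#' regression_reference_forecast(pos, generate_series(pos))  # 4042.72
#' @export
regression_reference_forecast <- function(spec, series) {
  stopifnot(inherits(spec, "trend_spec"))
  y <- as.numeric(series)
  if (length(y) != spec$length) {
    stop(sprintf("series length %d does not match spec length %d",
                 length(y), spec$length))
  }
  if (spec$consistency == "consistent") {
    return(deterministic_value(spec, spec$length + 1L))
  }
  t <- seq_along(y)
  fit <- stats::lm(y ~ t)
  unname(stats::predict(fit, newdata = data.frame(t = spec$length + 1L)))
}

#' Multiplicative noise for a reference forecast
#'
#' Weights a predicted value by the same random process as the behavioral
#' model: `value * (1 + kp * xi)` with `xi` standard normal, fresh per
#' draw. Represents individual variability around the regression-predicted
#' next trend value.
#'
#' @param value Predicted value(s) in pounds.
#' @param kp Dimensionless noise coefficient, `>= 0`.
#' @param n Number of draws per value.
#' @return Numeric vector of noisy values.
#' @export
noisy_reference <- function(value, kp, n = 1L) {
  stopifnot(is.numeric(value), is.numeric(kp), kp >= 0, n >= 1)
  if (n == 1L) value * (1 + kp * stats::rnorm(length(value)))
  else value * (1 + kp * stats::rnorm(n))
}

#' One-step AR(1) forecast
#'
#' Fits the first-order autoregression `y_t = c + phi * y_(t-1) + e_t`
#' (intercept included) and returns the one-step-ahead forecast
#' `c + phi * y_T`. The default `"cls"` method is conditional least
#' squares — the exact linear least-squares fit of `y_t` on `y_(t-1)`,
#' conditioning on the first observation — which is deterministic and has a
#' closed form. `"ml"` uses full maximum likelihood via [stats::arima()].
#' A series that is constant to machine precision forecasts the constant.
#'
#' @param series A `salary_series` or numeric vector, length `>= 3`.
#' @param method `"cls"` (conditional least squares, default) or `"ml"`.
#' @return The one-step-ahead forecast in pounds.
#' @export
arima_one_step <- function(series, method = c("cls", "ml")) {
  method <- match.arg(method)
  y <- as.numeric(series)
  n <- length(y)
  if (n < 3L) stop("'series' must have at least 3 observations")
  if (diff(range(y)) < sqrt(.Machine$double.eps) * max(1, abs(y[1]))) {
    return(y[n])
  }
  if (method == "cls") {
    y1 <- y[-n]
    y2 <- y[-1]
    fit <- stats::lm(y2 ~ y1)
    b <- stats::coef(fit)
    return(unname(b[1] + b[2] * y[n]))
  }
  fit <- stats::arima(y, order = c(1L, 0L, 0L), method = "ML")
  as.numeric(stats::predict(fit, n.ahead = 1L)$pred)
}

# In-sample one-step sum of squared errors of simple exponential smoothing
# with the level initialized to the first observation.
.ses_sse <- function(y, alpha) {
  level <- y[1]
  sse <- 0
  for (t in 2:length(y)) {
    sse <- sse + (y[t] - level)^2
    level <- alpha * y[t] + (1 - alpha) * level
  }
  sse
}

.ses_level <- function(y, alpha) {
  level <- y[1]
  for (t in 2:length(y)) level <- alpha * y[t] + (1 - alpha) * level
  level
}

#' One-step simple exponential smoothing forecast
#'
#' Recursive level estimate `l_t = alpha * y_t + (1 - alpha) * l_(t-1)`,
#' initialized at the first observation. Unless `alpha` is supplied, the
#' smoothing parameter is chosen to minimize the in-sample one-step sum of
#' squared errors over `[0.01, 0.99]`. The forecast is the final smoothed
#' level.
#'
#' @param series A `salary_series` or numeric vector, length `>= 2`.
#' @param alpha Optional fixed smoothing parameter in `(0, 1]`; `NULL`
#'   (default) optimizes it.
#' @return The one-step-ahead forecast in pounds.
#' @export
ses_one_step <- function(series, alpha = NULL) {
  y <- as.numeric(series)
  if (length(y) < 2L) stop("'series' must have at least 2 observations")
  if (is.null(alpha)) {
    if (diff(range(y)) == 0) return(y[1])
    alpha <- stats::optimize(function(a) .ses_sse(y, a),
                             interval = c(0.01, 0.99), tol = 1e-8)$minimum
  } else {
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  }
  .ses_level(y, alpha)
}

#' Comparator forecast dispatcher
#'
#' Computes the one-step forecast of a named comparator model for one
#' presented series.
#'
#' @param kind `"regression_next"`, `"arima_100"` or `"exp_smoothing"`.
#' @param spec The [trend_spec()] of the series (needed by
#'   `"regression_next"`).
#' @param series The presented series.
#' @return Forecast in pounds (deterministic given the series; noise is
#'   applied separately via [noisy_reference()]).
#' @export
comparator_forecast <- function(kind = c("regression_next", "arima_100",
                                         "exp_smoothing"),
                                spec, series) {
  kind <- match.arg(kind)
  switch(kind,
         regression_next = regression_reference_forecast(spec, series),
         arima_100 = arima_one_step(series),
         exp_smoothing = ses_one_step(series))
}
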