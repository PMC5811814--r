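# Shared fixtures: zero-noise series for the closed-form checks.
zero_noise_spec <- function(direction, consistency = "consistent") {
  trend_spec(direction, consistency, noise_variance = 0)
}

zero_noise_series <- function(direction, consistency = "consistent") {
  generate_series(zero_noise_spec(direction, consistency))
}

# Brute-force conditional-least-squares AR(1) oracle: numerically minimize
# sum_{t=2}^T (y_t - c - phi * y_{t-1})^2, independent of the linear-algebra
# path used by the package. For any phi the optimal intercept is the mean of
# the one-step residuals, so the objective is profiled down to a line search
# over phi.
arima_cls_oracle <- function(y) {
  n <- length(y)
  y1 <- y[-n]
  y2 <- y[-1]
  profile_css <- function(phi) {
    c_opt <- mean(y2 - phi * y1)
    sum((y2 - c_opt - phi * y1)^2)
  }
  phi <- stats::optimize(profile_css, interval = c(-2, 2), tol = 1e-12)$minimum
  c_opt <- mean(y2 - phi * y1)
  unname(c_opt + phi * y[n])
}

# Hand-unrolled simple exponential smoothing level for a fixed alpha.
ses_oracle <- function(y, alpha) {
  level <- y[1]
  for (t in 2:length(y)) level <- alpha * y[t] + (1 - alpha) * level
  level
}
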