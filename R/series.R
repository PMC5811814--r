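#' Specification of an experimental salary series
#'
#' Construct the parametric description of one of the three generating
#' equations used as stimuli: a linear positive trend
#' (\eqn{Y(t) = 3000 + 21.28 t + n}), a linear negative trend
#' (\eqn{Y(t) = 4000 - 21.28 t + n}), or a stationary series
#' (\eqn{Y(t) = 3500 + n}), with \eqn{n} Gaussian noise of mean 0 and
#' variance `noise_variance`. Consistent series have 48 monthly values;
#' inconsistent series append a 49th value of exactly 3,500, breaking the
#' trend.
#'
#' @param direction Trend direction: `"positive"`, `"negative"` or
#'   `"stationary"`.
#' @param consistency `"consistent"` (48 points on the trend) or
#'   `"inconsistent"` (49 points, the last fixed at 3,500).
#' @param noise_variance Variance (pounds squared) of the additive Gaussian
#'   noise; default 10. Must be non-negative.
#' @return An object of class `trend_spec`: a list with fields `direction`,
#'   `consistency`, `intercept`, `slope`, `noise_variance` and `length`.
#' @examples
#' trend_spec("positive", "consistent")
#' trend_spec("negative", "inconsistent", noise_variance = 0)
#' @export
trend_spec <- function(direction = c("positive", "negative", "stationary"),
                       consistency = c("consistent", "inconsistent"),
                       noise_variance = 10) {
  direction <- match.arg(direction)
  consistency <- match.arg(consistency)
  if (!is.numeric(noise_variance) || length(noise_variance) != 1L ||
      is.na(noise_variance) || noise_variance < 0) {
    stop("'noise_variance' must be a single non-negative number")
  }
  structure(
    list(
      direction = direction,
      consistency = consistency,
      intercept = switch(direction,
                         positive = 3000, negative = 4000, stationary = 3500),
      slope = switch(direction,
                     positive = 21.28, negative = -21.28, stationary = 0),
      noise_variance = noise_variance,
      length = if (consistency == "consistent") 48L else 49L
    ),
    class = "trend_spec"
  )
}

#' @export
print.trend_spec <- function(x, ...) {
  cat(sprintf("Trend specification: %s, %s\n", x$direction, x$consistency))
  cat(sprintf("  Y(t) = %.0f %+.2f * t + n,  t = 1..%d\n",
              x$intercept, x$slope,
              if (x$consistency == "consistent") x$length else x$length - 1L))
  if (x$consistency == "inconsistent")
    cat(sprintf("  appended point: Y(%d) = 3500 exactly\n", x$length))
  cat(sprintf("  noise: Gaussian, mean 0, variance %g\n", x$noise_variance))
  invisible(x)
}

#' Noise-free value of a generating equation
#'
#' Evaluates the deterministic component `intercept + slope * t` of a trend
#' specification. For an inconsistent series the appended point (month 49)
#' returns exactly 3,500 regardless of direction. `t = length + 1` is
#' permitted so the true next trend value can be computed.
#'
#' @param spec A [trend_spec()].
#' @param t Month index (1-based); may be a vector. Valid range is
#'   `1..spec$length + 1`.
#' @return Numeric vector of deterministic values in pounds.
#' @examples
#' pos <- trend_spec("positive", "consistent")
#' deterministic_value(pos, 48)  # 4021.44
#' deterministic_value(pos, 49)  # true next value, 4042.72
#' @export
deterministic_value <- function(spec, t) {
  stopifnot(inherits(spec, "trend_spec"))
  if (!is.numeric(t) || any(is.na(t)) || any(t != floor(t))) {
    stop("'t' must be whole-number month indices")
  }
  if (any(t < 1) || any(t > spec$length + 1L)) {
    stop(sprintf("'t' must lie in 1..%d", spec$length + 1L))
  }
  val <- spec$intercept + spec$slope * t
  if (spec$consistency == "inconsistent") {
    val[t == spec$length] <- 3500
  }
  val
}

#' Generate one experimental salary series
#'
#' Draws a series of monthly salary values from a trend specification:
#' the deterministic trend plus independent Gaussian noise of the specified
#' variance at every on-trend month. The appended 49th point of an
#' inconsistent series is exactly 3,500 and carries no noise.
#'
#' @param spec A [trend_spec()].
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first so generation is a pure function of `(spec, seed)`. When `NULL`
#'   the current RNG stream is used.
#' @return A `salary_series`: a numeric vector of length `spec$length`
#'   (months are the 1-based positions) carrying the spec as an attribute.
#' @examples
#' s <- generate_series(trend_spec("stationary", "consistent"), seed = 1)
#' series_mean(s)
#' @export
generate_series <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "trend_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_noisy <- if (spec$consistency == "consistent") spec$length else spec$length - 1L
  t_all <- seq_len(spec$length)
  values <- spec$intercept + spec$slope * t_all
  values[seq_len(n_noisy)] <- values[seq_len(n_noisy)] +
    stats::rnorm(n_noisy, mean = 0, sd = sqrt(spec$noise_variance))
  if (spec$consistency == "inconsistent") values[spec$length] <- 3500
  structure(values, class = "salary_series", spec = spec)
}

#' @export
print.salary_series <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Salary series (%s, %s), %d months\n",
              spec$direction, spec$consistency, length(x)))
  print(utils::head(as.numeric(x), 6))
  if (length(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.salary_series <- function(x, ...) {
  data.frame(month = seq_along(x), value = as.numeric(x))
}

#' Arithmetic mean of a salary series
#'
#' @param series A `salary_series` or plain numeric vector of presented
#'   values.
#' @return The mean of all presented values, in pounds.
#' @export
series_mean <- function(series) {
  x <- as.numeric(series)
  if (length(x) == 0L) stop("'series' must be non-empty")
  mean(x)
}
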