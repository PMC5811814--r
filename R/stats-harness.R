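#' Unrelated (independent-samples) t test with effect size r
#'
#' Student's pooled-variance two-sample t test (equal variances assumed, as
#' licensed by Levene's test on the simulated cells), with
#' `df = n_a + n_b - 2`, a two-sided p value, and the correlation-metric
#' effect size `r = sqrt(t^2 / (t^2 + df))`.
#'
#' @param a,b Numeric samples, each of length `>= 2`.
#' @return An `adam_test` object: list with `t`, `df`, `p`, `r`.
#' @examples
#' unrelated_t(c(1, 2, 3), c(2, 3, 4))
#' @export
unrelated_t <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample must have at least 2 observations")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  structure(list(t = t, df = df, p = tt$p.value,
                 r = effect_size_r(t, df)),
            class = "adam_test")
}

#' @export
print.adam_test <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g, r = %.3f\n", x$df, x$t, x$p, x$r))
  invisible(x)
}

#' Effect size r from a t statistic
#'
#' `r = sqrt(t^2 / (t^2 + df))`: symmetric in the sign of t, strictly
#' increasing in `|t|`, and in `[0, 1)`.
#'
#' @param t t statistic.
#' @param df Degrees of freedom, `>= 1`.
#' @return Effect size r.
#' @examples
#' effect_size_r(-2.86, 3238)  # about .05
#' @export
effect_size_r <- function(t, df) {
  stopifnot(is.numeric(t), is.numeric(df))
  if (any(df < 1)) stop("'df' must be >= 1")
  sqrt(t^2 / (t^2 + df))
}

#' Levene's test for equality of variances (two samples)
#'
#' Levene's test with the mean as the center (the classical form: a one-way
#' ANOVA on absolute deviations from the group means), via
#' [car::leveneTest()].
#'
#' @param a,b Numeric samples, each of length `>= 2`.
#' @return An `adam_test` object with the F statistic in `t` slot `F`,
#'   numerator/denominator dfs, and p value: list with `F`, `df1`, `df2`,
#'   `p`.
#' @export
levene_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample must have at least 2 observations")
  }
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lt <- car::leveneTest(y, g, center = mean)
  structure(list(F = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
                 p = lt[1, "Pr(>F)"]),
            class = "adam_levene")
}

#' @export
print.adam_levene <- function(x, ...) {
  cat(sprintf("Levene F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Ratio of sample standard deviations
#'
#' `SD(a) / SD(b)`, the dispersion diagnostic used to check that simulated
#' perceptual variability matches a reference sample.
#'
#' @param a,b Numeric samples, each of length `>= 2`.
#' @return The SD ratio.
#' @export
sd_ratio <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sdb <- stats::sd(b)
  if (sdb == 0) stop("SD of 'b' is zero; ratio undefined")
  stats::sd(a) / sdb
}

#' Between-subjects factorial ANOVA with epsilon-squared effect sizes
#'
#' Fits a fully crossed between-subjects ANOVA (all main effects and
#' interactions) on a balanced design and reports, per effect, the degrees
#' of freedom, F, p, and the effect size
#' `epsilon^2 = (SS_effect - df_effect * MS_error) / SS_total`.
#' If the response is constant (zero total sum of squares), all F and
#' epsilon-squared values are reported as 0 by convention.
#'
#' @param data Long-format data frame of observations.
#' @param factors Character vector of factor column names.
#' @param response Name of the numeric response column.
#' @return A data frame with one row per effect plus `Residuals` and
#'   `Total` rows: columns `source`, `df`, `sum_sq`, `F`, `p`,
#'   `epsilon_sq`.
#' @export
factorial_anova <- function(data, factors, response) {
  stopifnot(is.data.frame(data), length(factors) >= 1L,
            all(factors %in% names(data)), response %in% names(data))
  for (f in factors) data[[f]] <- factor(data[[f]])
  counts <- table(data[factors])
  if (any(counts == 0L)) stop("design has empty cells")
  if (length(unique(as.vector(counts))) != 1L) stop("design is unbalanced")

  fml <- stats::reformulate(paste(factors, collapse = "*"), response)
  fit <- stats::aov(fml, data = data)
  # a constant response triggers an F-reliability warning; the degenerate
  # case is reported via the documented zero convention below
  at <- suppressWarnings(stats::anova(fit))
  src <- rownames(at)
  ss <- at[["Sum Sq"]]
  ss_total <- sum(ss)
  resid_row <- which(src == "Residuals")
  ms_error <- at[resid_row, "Mean Sq"]

  eff <- setdiff(seq_along(src), resid_row)
  Fv <- at[eff, "F value"]
  pv <- at[eff, "Pr(>F)"]
  eps <- (ss[eff] - at[eff, "Df"] * ms_error) / ss_total
  if (stats::var(data[[response]]) == 0) {
    ss_total <- 0
    Fv[] <- 0
    pv[] <- 1
    eps[] <- 0
  }
  out <- data.frame(
    source = c(trimws(src[eff]), "Residuals", "Total"),
    df = c(at[eff, "Df"], at[resid_row, "Df"], sum(at[["Df"]])),
    sum_sq = c(ss[eff], ss[resid_row], ss_total),
    F = c(Fv, NA, NA),
    p = c(pv, NA, NA),
    epsilon_sq = c(eps, NA, NA),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Split-half cross-validation of model fit
#'
#' Randomly halves the response sample and the prediction sample for one
#' design cell, then runs the 2 x 2 between-subjects ANOVA with factors
#' series (data vs. model) and subsample. A good and consistent fit shows a
#' non-significant series main effect (no overall data-model difference)
#' and a non-significant interaction (the fit does not differ between
#' halves).
#'
#' Uses the current RNG stream for the random split; call `set.seed()`
#' first for a reproducible split.
#'
#' @param responses Numeric sample of responses (even length).
#' @param predictions Numeric sample of model predictions, same length.
#' @return The [factorial_anova()] rows for the series main effect and the
#'   series-by-subsample interaction.
#' @export
split_half_check <- function(responses, predictions) {
  stopifnot(is.numeric(responses), is.numeric(predictions))
  n <- length(responses)
  if (length(predictions) != n) stop("samples must have the same size")
  if (n < 4L || n %% 2L != 0L) stop("samples must have even length >= 4")
  half <- function() {
    s <- rep(2L, n)
    s[sample.int(n, n %/% 2L)] <- 1L
    s
  }
  d <- data.frame(
    y = c(responses, predictions),
    series = rep(c("data", "model"), each = n),
    subsample = factor(c(half(), half()))
  )
  tab <- factorial_anova(d, c("series", "subsample"), "y")
  tab[tab$source %in% c("series", "series:subsample"), ]
}
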