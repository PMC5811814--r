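#' The adaptive anchoring model (ADAM)
#'
#' Constructs an ADAM model object. The model produces a behavioral response
#' to a presented salary series as
#' \deqn{BR = SW \times EA \times (1 + k_p x_p),}
#' where `SW = exp(-(S - T))` is the similarity weight between an idealized
#' stimulus item `S` (0.35 for static presentation; the normalized last
#' series value for either dynamic presentation) and an idealized task item
#' `T` (0.35 for average-estimation judgment; the normalized last value for
#' forecasting), `EA` is the experience-dependent anchor (3,500 — the series
#' mean — for static presentation; the last presented value for dynamic
#' presentation), and `x_p` is a standard-normal perceptual-noise draw scaled
#' by the dimensionless coefficient `kp`.
#'
#' Normalization maps pounds into the unit interval by division by
#' `normalization`; the defaults satisfy
#' `static_stimulus == static_anchor / normalization` (0.35 = 3500 / 10000),
#' the unique linear map consistent with the model constants.
#'
#' @param kp Dimensionless perceptual-noise coefficient, `>= 0`;
#'   default 0.04. With `kp = 0` the model is deterministic.
#' @param normalization Currency value mapped to 1 by normalization;
#'   default 10,000 pounds.
#' @param static_stimulus Idealized stimulus/task item used for static
#'   presentation and for the judgment task; default 0.35.
#' @param static_anchor Anchor used under static presentation; default
#'   3,500 pounds (the series mean).
#' @return An object of class `adam`.
#' @examples
#' m <- adam(kp = 0)
#' s <- generate_series(trend_spec("positive", "consistent",
#'                                 noise_variance = 0))
#' predict(m, s, mode = "static", task = "forecast")
#' @export
adam <- function(kp = 0.04, normalization = 10000,
                 static_stimulus = 0.35, static_anchor = 3500) {
  stopifnot(is.numeric(kp), length(kp) == 1L, kp >= 0,
            is.numeric(normalization), normalization > 0,
            is.numeric(static_anchor), static_anchor > 0)
  if (!isTRUE(all.equal(static_stimulus, static_anchor / normalization))) {
    stop("'static_stimulus' must equal static_anchor / normalization")
  }
  structure(
    list(kp = kp, normalization = normalization,
         static_stimulus = static_stimulus, static_anchor = static_anchor),
    class = "adam"
  )
}

#' @export
print.adam <- function(x, ...) {
  cat("Adaptive anchoring model (ADAM)\n")
  cat("  BR = exp(-(S - T)) * EA * (1 + kp * x_p)\n")
  cat(sprintf("  kp = %g, normalization = %g, static item = %g, static anchor = %g\n",
              x$kp, x$normalization, x$static_stimulus, x$static_anchor))
  invisible(x)
}

#' @export
coef.adam <- function(object, ...) {
  c(kp = object$kp, normalization = object$normalization,
    static_stimulus = object$static_stimulus,
    static_anchor = object$static_anchor)
}

.adam_modes <- c("static", "historic_dynamic", "momentary_dynamic")
.adam_tasks <- c("forecast", "judgment")

#' Normalize a monetary value into the unit interval
#'
#' @param value Value(s) in pounds; must lie in `[0, normalization]`.
#' @param model An [adam()] model (supplies the normalization constant).
#' @return `value / normalization`, in `[0, 1]`.
#' @examples
#' normalize_value(3500, adam())  # 0.35
#' @export
normalize_value <- function(value, model = adam()) {
  stopifnot(inherits(model, "adam"), is.numeric(value))
  if (any(value < 0 | value > model$normalization)) {
    stop(sprintf("values must lie in [0, %g] to map into the unit interval",
                 model$normalization))
  }
  value / model$normalization
}

#' Idealized stimulus item S
#'
#' Static presentation yields the fixed item 0.35 (the normalized series
#' mean); both dynamic presentations yield the normalized last presented
#' value — the model does not distinguish historic- from momentary-dynamic
#' presentation.
#'
#' @param model An [adam()] model.
#' @param series Presented `salary_series` (or numeric vector).
#' @param mode `"static"`, `"historic_dynamic"` or `"momentary_dynamic"`.
#' @return A value in `[0, 1]`.
#' @export
stimulus_item <- function(model, series, mode = .adam_modes) {
  mode <- match.arg(mode, .adam_modes)
  x <- as.numeric(series)
  if (length(x) == 0L) stop("'series' must be non-empty")
  if (mode == "static") model$static_stimulus
  else normalize_value(x[length(x)], model)
}

#' Idealized task item T
#'
#' The judgment (average-estimation) task yields the fixed item 0.35; the
#' forecasting task yields the normalized last presented value.
#'
#' @inheritParams stimulus_item
#' @param task `"forecast"` or `"judgment"`.
#' @return A value in `[0, 1]`.
#' @export
task_item <- function(model, series, task = .adam_tasks) {
  task <- match.arg(task, .adam_tasks)
  x <- as.numeric(series)
  if (length(x) == 0L) stop("'series' must be non-empty")
  if (task == "judgment") model$static_stimulus
  else normalize_value(x[length(x)], model)
}

#' Exponential stimulus-task similarity weight
#'
#' `SW = exp(-(S - T))` on the signed (not absolute) distance between the
#' idealized stimulus and task items, so the direction of the mismatch is
#' preserved: `similarity_weight(S, T) * similarity_weight(T, S) == 1`.
#'
#' @param S,T Idealized items in `[0, 1]`.
#' @return A positive similarity weight.
#' @examples
#' similarity_weight(0.35, 0.35)      # 1
#' similarity_weight(0.35, 0.402144)  # > 1
#' @export
similarity_weight <- function(S, T) {
  stopifnot(is.numeric(S), is.numeric(T),
            all(S >= 0 & S <= 1), all(T >= 0 & T <= 1))
  exp(-(S - T))
}

#' Experience-dependent anchor EA
#'
#' Static presentation anchors on 3,500 pounds (the series mean); both
#' dynamic presentations anchor on the last presented value.
#'
#' @inheritParams stimulus_item
#' @return Anchor in pounds.
#' @export
experience_anchor <- function(model, series, mode = .adam_modes) {
  mode <- match.arg(mode, .adam_modes)
  x <- as.numeric(series)
  if (length(x) == 0L) stop("'series' must be non-empty")
  if (mode == "static") model$static_anchor else x[length(x)]
}

#' Deterministic mean response of ADAM
#'
#' Returns `SW * EA`, the expected behavioral response (the exact response
#' when `kp = 0`).
#'
#' @param object An [adam()] model.
#' @param series Presented `salary_series` (or numeric vector).
#' @param mode Presentation mode (see [stimulus_item()]).
#' @param task Judgment task (see [task_item()]).
#' @param ... Unused.
#' @return Expected response in pounds.
#' @export
predict.adam <- function(object, series, mode = .adam_modes,
                         task = .adam_tasks, ...) {
  mode <- match.arg(mode, .adam_modes)
  task <- match.arg(task, .adam_tasks)
  S <- stimulus_item(object, series, mode)
  T <- task_item(object, series, task)
  similarity_weight(S, T) * experience_anchor(object, series, mode)
}

#' Stochastic behavioral response(s) to one presented series
#'
#' Draws `n` responses `SW * EA * (1 + kp * x_p)` with independent
#' standard-normal `x_p` per response (one simulated agent per draw). Uses
#' the current RNG stream.
#'
#' @inheritParams predict.adam
#' @param model An [adam()] model.
#' @param n Number of responses to draw.
#' @return Numeric vector of `n` responses in pounds.
#' @export
behavioral_response <- function(model, series, mode = .adam_modes,
                                task = .adam_tasks, n = 1L) {
  stopifnot(inherits(model, "adam"), n >= 1)
  mu <- predict.adam(model, series, mode, task)
  mu * (1 + model$kp * stats::rnorm(n))
}

#' Simulate one design cell
#'
#' Generates `n` behavioral responses for a (mode, task, trend) cell. By
#' default each replicate regenerates the series noise (a fresh stimulus per
#' simulated agent); with `fixed_series = TRUE` a single series is generated
#' and response variability comes from the perceptual noise `x_p` alone.
#'
#' @param model An [adam()] model.
#' @param spec A [trend_spec()] describing the cell's series.
#' @param mode Presentation mode.
#' @param task Judgment task.
#' @param n Number of replicates, `>= 1`.
#' @param seed Optional integer seed making the cell reproducible in
#'   isolation.
#' @param fixed_series If `TRUE`, one series is shared by all replicates.
#' @return Numeric vector of `n` responses.
#' @export
simulate_condition <- function(model, spec, mode = .adam_modes,
                               task = .adam_tasks, n = 90L, seed = NULL,
                               fixed_series = FALSE) {
  stopifnot(inherits(model, "adam"), inherits(spec, "trend_spec"))
  mode <- match.arg(mode, .adam_modes)
  task <- match.arg(task, .adam_tasks)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (fixed_series) {
    series <- generate_series(spec)
    return(behavioral_response(model, series, mode, task, n = n))
  }
  vapply(seq_len(n), function(i) {
    behavioral_response(model, generate_series(spec), mode, task, n = 1L)
  }, numeric(1))
}

#' @rdname simulate_condition
#' @param object An [adam()] model (for the `simulate` method).
#' @param nsim Number of replicates.
#' @param ... Unused.
#' @export
simulate.adam <- function(object, nsim = 1L, seed = NULL, spec,
                          mode = .adam_modes, task = .adam_tasks,
                          fixed_series = FALSE, ...) {
  simulate_condition(object, spec, mode, task, n = nsim, seed = seed,
                     fixed_series = fixed_series)
}

#' Recover the perceptual-noise coefficient from simulated responses
#'
#' Under the model, responses within a cell have mean `SW * EA` and standard
#' deviation `SW * EA * kp`, so the within-cell SD/mean ratio estimates
#' `kp`. The estimate is the mean ratio across all cells of a response
#' table (ADAM rows only).
#'
#' @param table A response table from [run_full_design()].
#' @return List with `kp` (the pooled estimate) and `by_cell` (per-cell
#'   ratios).
#' @export
estimate_kp <- function(table) {
  stopifnot(is.data.frame(table))
  tab <- table[table$model == "adam", , drop = FALSE]
  if (nrow(tab) == 0L) stop("table contains no ADAM responses")
  cell <- interaction(tab$mode, tab$direction, tab$consistency, tab$task,
                      drop = TRUE)
  ratios <- tapply(tab$response, cell,
                   function(x) stats::sd(x) / mean(x))
  list(kp = mean(ratios), by_cell = ratios)
}
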