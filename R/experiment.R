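.all_models <- c("adam", "regression_next", "arima_100", "exp_smoothing")

# Deterministic per-cell child seed below 2^31, so any single cell can be
# replayed in isolation from the run metadata.
.cell_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 7919) %% 2147483629 + 1)
}

#' Run the full simulated factorial design
#'
#' Simulates the 3 (presentation mode) x 3 (trend direction) x 2 (trend
#' consistency) design for the requested tasks and models, `n_per_condition`
#' replicates per cell. By default each replicate regenerates the stimulus
#' series, and all models requested for a cell respond to the same
#' replicate series, so model comparisons are made on identical stimuli.
#'
#' ADAM responds in every cell; the comparator forecasters
#' (`"regression_next"`, `"arima_100"`, `"exp_smoothing"`) respond only in
#' forecasting cells. The regression comparator carries the same
#' multiplicative perceptual noise as ADAM (`value * (1 + kp * xi)`); the
#' ARIMA and exponential-smoothing forecasts are pure model forecasts
#' unless `comparator_noise = TRUE`.
#'
#' Errors are scored against the cell reference: the regression-predicted
#' next trend value for forecasting (see
#' [regression_reference_forecast()]), and the true mean 3,500 for
#' average-estimation judgment.
#'
#' @param model An [adam()] model; its `kp` also drives the
#'   regression-comparator noise.
#' @param n_per_condition Replicates per design cell (default 90).
#' @param models Character vector from `"adam"`, `"regression_next"`,
#'   `"arima_100"`, `"exp_smoothing"`.
#' @param tasks Tasks to run: subset of `"forecast"`, `"judgment"`.
#' @param noise_variance Series noise variance (pounds squared), default 10.
#' @param fixed_series If `TRUE`, one series per cell is shared by all
#'   replicates (variability from perceptual noise only).
#' @param master_seed Integer master seed; per-cell seeds are derived from
#'   it deterministically.
#' @param comparator_noise If `TRUE`, ARIMA and exponential-smoothing
#'   forecasts are also weighted by `(1 + kp * xi)`.
#' @return A `response_table`: a long-format data frame with one row per
#'   (cell, model, replicate) holding `response`, `reference`,
#'   `signed_error` and `abs_error`, with the run configuration attached as
#'   attribute `metadata`.
#' @examples
#' tab <- run_full_design(adam(kp = 0), n_per_condition = 2,
#'                        noise_variance = 0, master_seed = 1)
#' nrow(tab)  # 18 cells x 2 tasks x 2 replicates
#' @export
run_full_design <- function(model = adam(), n_per_condition = 90L,
                            models = "adam",
                            tasks = c("forecast", "judgment"),
                            noise_variance = 10, fixed_series = FALSE,
                            master_seed = 1L, comparator_noise = FALSE) {
  stopifnot(inherits(model, "adam"))
  if (!is.numeric(n_per_condition) || n_per_condition < 1) {
    stop("'n_per_condition' must be >= 1")
  }
  n <- as.integer(n_per_condition)
  if (length(models) == 0L) stop("'models' must be non-empty")
  bad <- setdiff(models, .all_models)
  if (length(bad)) {
    stop("unknown model name(s): ", paste(bad, collapse = ", "))
  }
  tasks <- match.arg(tasks, several.ok = TRUE)

  cells <- expand.grid(mode = .adam_modes,
                       direction = c("stationary", "positive", "negative"),
                       consistency = c("consistent", "inconsistent"),
                       task = tasks,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  comparators <- setdiff(models, "adam")

  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    seed_i <- .cell_seed(master_seed, i)
    set.seed(seed_i)
    spec <- trend_spec(cl$direction, cl$consistency,
                       noise_variance = noise_variance)

    # Draw all replicate series first, then per-model noise streams, so the
    # stimuli are identical whichever model subset is requested.
    if (fixed_series) {
      series_list <- rep(list(generate_series(spec)), n)
    } else {
      series_list <- lapply(seq_len(n), function(r) generate_series(spec))
    }
    reference <- if (cl$task == "forecast") {
      vapply(series_list, function(s) regression_reference_forecast(spec, s),
             numeric(1))
    } else {
      rep(3500, n)
    }

    cell_rows <- list()
    if ("adam" %in% models) {
      mu <- vapply(series_list, function(s) {
        predict(model, s, mode = cl$mode, task = cl$task)
      }, numeric(1))
      resp <- mu * (1 + model$kp * stats::rnorm(n))
      cell_rows$adam <- resp
    }
    if (cl$task == "forecast") {
      for (cm in comparators) {
        fc <- vapply(series_list, function(s) comparator_forecast(cm, spec, s),
                     numeric(1))
        noisy <- cm == "regression_next" || comparator_noise
        if (noisy) fc <- fc * (1 + model$kp * stats::rnorm(n))
        cell_rows[[cm]] <- fc
      }
    }
    if (length(cell_rows) == 0L) next

    cell_df <- do.call(rbind, lapply(names(cell_rows), function(nm) {
      data.frame(mode = cl$mode, direction = cl$direction,
                 consistency = cl$consistency, task = cl$task,
                 model = nm, replicate = seq_len(n), seed = seed_i,
                 response = cell_rows[[nm]], reference = reference,
                 stringsAsFactors = FALSE)
    }))
    out[[i]] <- cell_df
  }

  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$signed_error <- tab$response - tab$reference
  tab$abs_error <- abs(tab$signed_error)
  attr(tab, "metadata") <- list(
    params = as.list(coef(model)),
    n_per_condition = n, models = models, tasks = tasks,
    noise_variance = noise_variance, fixed_series = fixed_series,
    comparator_noise = comparator_noise, master_seed = master_seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  class(tab) <- c("response_table", class(tab))
  tab
}

#' Signed forecasting error
#'
#' `response - reference`, where the reference is the regression-predicted
#' next trend value; under-prediction of an upward trend is negative
#' (trend damping).
#'
#' @param response Response value(s) in pounds.
#' @param reference Predicted next trend value(s) in pounds.
#' @return Signed error(s) in pounds.
#' @export
forecast_error <- function(response, reference) response - reference

#' Signed average-estimation error
#'
#' `response - 3500`: error of the judged average relative to the true
#' mean, which is taken as 3,500 for all series.
#'
#' @param response Response value(s) in pounds.
#' @param true_mean Reference mean; default 3,500.
#' @return Signed error(s) in pounds.
#' @export
estimation_error <- function(response, true_mean = 3500) response - true_mean

#' Per-cell summary of a response table
#'
#' One row per (mode, direction, consistency, task, model) with the count
#' and the mean and SD of responses, signed errors and absolute errors.
#' The SD of a single-record cell is reported as 0 by convention.
#'
#' @param table A `response_table` from [run_full_design()].
#' @return A data frame of per-cell summaries.
#' @export
summarize_design <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("'table' is empty")
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  key <- c("mode", "direction", "consistency", "task", "model")
  agg <- function(col, fn, nm) {
    a <- stats::aggregate(table[[col]], table[key], fn)
    names(a)[ncol(a)] <- nm
    a
  }
  res <- agg("response", length, "n")
  for (spec in list(c("response", "mean_response"), c("signed_error", "mean_signed"),
                    c("abs_error", "mean_abs"))) {
    res <- merge(res, agg(spec[1], mean, spec[2]), by = key)
  }
  for (spec in list(c("response", "sd_response"), c("signed_error", "sd_signed"),
                    c("abs_error", "sd_abs"))) {
    res <- merge(res, agg(spec[1], sd0, spec[2]), by = key)
  }
  res[order(res$task, res$consistency, res$direction, res$mode, res$model), ]
}

#' Write a response table, its summary, and run metadata to disk
#'
#' Writes `responses.csv` (one row per response record), `summary.csv`
#' (per-cell summaries) and `metadata.json` (the full run configuration and
#' seeds, sufficient to reproduce the run).
#'
#' @param table A `response_table` from [run_full_design()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_response_table <- function(table, dir) {
  stopifnot(is.data.frame(table))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("responses.csv", "summary.csv", "metadata.json"))
  utils::write.csv(as.data.frame(table), paths[1], row.names = FALSE)
  utils::write.csv(summarize_design(table), paths[2], row.names = FALSE)
  meta <- attr(table, "metadata")
  if (is.null(meta)) meta <- list()
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
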