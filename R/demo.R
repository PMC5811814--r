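#' Worked example of the deterministic model
#'
#' Computes, for the zero-noise positive consistent trend with `kp = 0`,
#' the idealized stimulus item S, task item T, similarity weight SW,
#' experience-dependent anchor EA, and behavioral response BR for all six
#' presentation-mode by task combinations, together with the cell
#' reference and signed error. Useful as a hand-checkable worked example:
#' every number follows from the closed forms.
#'
#' @param direction Trend direction of the demonstration series
#'   (default `"positive"`).
#' @return A data frame with one row per mode x task combination.
#' @examples
#' adam_demo()
#' @export
adam_demo <- function(direction = c("positive", "negative", "stationary")) {
  direction <- match.arg(direction)
  model <- adam(kp = 0)
  spec <- trend_spec(direction, "consistent", noise_variance = 0)
  series <- generate_series(spec)
  grid <- expand.grid(mode = .adam_modes, task = .adam_tasks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mode <- grid$mode[i]
    task <- grid$task[i]
    S <- stimulus_item(model, series, mode)
    T <- task_item(model, series, task)
    SW <- similarity_weight(S, T)
    EA <- experience_anchor(model, series, mode)
    BR <- SW * EA
    reference <- if (task == "forecast") {
      regression_reference_forecast(spec, series)
    } else 3500
    data.frame(mode = mode, task = task, S = S, T = T, SW = SW, EA = EA,
               BR = BR, reference = reference,
               signed_error = BR - reference)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
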