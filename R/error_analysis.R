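#' Signed percent error of a speed prediction
#'
#' `100 (predicted - measured) / measured`: negative values are
#' underestimates of the measured speed, positive values overestimates.
#'
#' @param predicted Predicted speed(s), m/s.
#' @param measured Measured (ground-truth) speed(s), m/s; must be positive.
#'   `NA` propagates.
#' @return Signed percent error(s).
#' @examples
#' percent_error(1.1, 1.0)   # +10
#' percent_error(0.5, 1.0)   # -50
#' @export
percent_error <- function(predicted, measured) {
  if (any(!is.na(measured) & measured <= 0)) {
    abort("`measured` speeds must be positive (m/s).")
  }
  100 * (predicted - measured) / measured
}

#' Bin signed percent errors into decadal bins
#'
#' Width-10 histogram with edges anchored at multiples of 10, bins
#' closed on the left and open on the right, spanning the observed range.
#'
#' @param errors Numeric vector of signed percent errors (finite).
#' @return A tibble with `lower`, `upper` and `count`; counts sum to
#'   `length(errors)`.
#' @export
bin_errors <- function(errors) {
  if (!length(errors) || any(!is.finite(errors))) {
    abort("`errors` must be a non-empty vector of finite percent errors.")
  }
  lo <- floor(min(errors) / 10) * 10
  hi <- ceiling(max(errors) / 10) * 10
  if (hi == max(errors)) hi <- hi + 10  # right-open bins: top edge exclusive
  edges <- seq(lo, hi, by = 10)
  counts <- vapply(seq_len(length(edges) - 1L), function(i) {
    sum(errors >= edges[i] & errors < edges[i + 1L])
  }, 1L)
  tibble::tibble(lower = edges[-length(edges)], upper = edges[-1L], count = counts)
}

#' Summarise prediction errors for one model
#'
#' Computes signed percent errors for predicted/measured speed pairs and the
#' summary statistics used to compare models: the mean absolute error (the
#' headline "mean error" — the signed errors span both signs, so their
#' absolute mean is what measures accuracy), the signed mean, SD, range, and
#' a decadal histogram of the signed errors.
#'
#' @param data A data frame with the prediction and ground-truth columns.
#' @param predicted Name of the predicted-speed column (default `u_pred`).
#' @param measured Name of the measured-speed column (default `u_measured`).
#' @param model Label for the model being summarised.
#' @param gait Label for the gait subset ("all" when pooled).
#' @return A one-row tibble of class `error_summary`: `model`, `gait`, `n`,
#'   `mean_abs`, `mean_signed`, `sd`, `min`, `max`, and list columns
#'   `errors` (the signed percent errors) and `bins` (see [bin_errors()]).
#' @examples
#' d <- data.frame(u_pred = c(1.1, 0.9), u_measured = c(1, 1))
#' summarize_errors(d, model = "demo")
#' @export
summarize_errors <- function(data, predicted = "u_pred", measured = "u_measured",
                             model = "model", gait = "all") {
  data <- as.data.frame(data)
  for (col in c(predicted, measured)) {
    if (!col %in% names(data)) abort(paste0("Column '", col, "' not found."))
  }
  keep <- !is.na(data[[predicted]]) & !is.na(data[[measured]])
  if (!any(keep)) abort("No complete (predicted, measured) pairs to summarise.")
  errors <- percent_error(data[[predicted]][keep], data[[measured]][keep])
  bins <- bin_errors(errors)
  out <- tibble::tibble(
    model = model, gait = gait, n = sum(keep),
    mean_abs = mean(abs(errors)),
    mean_signed = mean(errors),
    sd = sd(errors),
    min = min(errors),
    max = max(errors),
    errors = list(errors),
    bins = list(bins)
  )
  class(out) <- c("error_summary", class(out))
  out
}

#' Evaluate speed models against ground-truth speeds
#'
#' Runs [predict_speeds()] for each requested model on trackways that carry
#' a measured speed and summarises the percent errors per model (and, when
#' `by_gait = TRUE`, per gait).
#'
#' @inheritParams predict_speeds
#' @param by_gait Also produce per-gait summaries alongside the pooled ones.
#' @return A tibble of [summarize_errors()] rows, one per model (and gait).
#' @export
evaluate_models <- function(data, profile = species_profile(),
                            gait_models = NULL,
                            models = c("species", "alexander", "thulborn_wade"),
                            by_gait = FALSE, level = 0.95) {
  data <- validate_trackways(data)
  data <- data[!is.na(data$u_measured), ]
  if (!nrow(data)) abort("No trackways with measured speeds to evaluate against.")
  preds <- predict_speeds(data, profile = profile, gait_models = gait_models,
                          models = models, level = level)
  pooled <- preds |>
    dplyr::group_by(.data$model) |>
    dplyr::group_map(~ summarize_errors(.x, model = .y$model)) |>
    dplyr::bind_rows()
  if (!by_gait) return(pooled)
  per_gait <- preds |>
    dplyr::filter(!is.na(.data$gait)) |>
    dplyr::group_by(.data$model, .data$gait) |>
    dplyr::group_map(~ summarize_errors(.x, model = .y$model, gait = .y$gait)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(pooled, per_gait)
}
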