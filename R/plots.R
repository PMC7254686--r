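#' Plot a calibrated gait model with its prediction band
#'
#' Scatter of the calibration records with the fitted line and the t-based
#' prediction interval ribbon over the observed stride range.
#'
#' @param object A `gait_model` or `gait_model_list`.
#' @param level Prediction-interval level, default 0.95.
#' @param n_grid Number of grid points for the ribbon.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_model <- function(object, level = 0.95, n_grid = 100, ...) {
  grid <- seq(object$l_range[1], object$l_range[2], length.out = n_grid)
  band <- predict_with_interval(object, grid, level = level)
  band$gait <- object$gait
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$l_stride)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "steelblue") +
    ggplot2::labs(
      x = "stride length (m)", y = "speed (m/s)",
      title = paste0("Speed-stride calibration: ", object$gait),
      subtitle = sprintf("U = %.2f l %+.2f, r² = %.2f, n = %d, %d%% PI",
                         object$slope, object$intercept, object$r2, object$n,
                         round(level * 100))
    )
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(x = .data$l_stride, y = .data$u_measured),
      alpha = 0.6
    )
  }
  p
}

#' @rdname autoplot.gait_model
#' @export
autoplot.gait_model_list <- function(object, level = 0.95, n_grid = 100, ...) {
  bands <- purrr::map_dfr(unclass(object), function(m) {
    grid <- seq(m$l_range[1], m$l_range[2], length.out = n_grid)
    b <- predict_with_interval(m, grid, level = level)
    b$gait <- m$gait
    b
  })
  pts <- purrr::map_dfr(unclass(object), function(m) {
    if (is.null(m$data)) return(NULL)
    tibble::tibble(l_stride = m$data$l_stride, u_measured = m$data$u_measured,
                   gait = m$gait)
  })
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$l_stride, color = .data$gait,
                                           fill = .data$gait)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = "stride length (m)", y = "speed (m/s)",
                  title = "Gait-wise speed-stride calibration",
                  subtitle = sprintf("%d%% prediction intervals", round(level * 100)))
  if (nrow(pts)) {
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(y = .data$u_measured), alpha = 0.5
    )
  }
  p
}

#' Plot a decadal error histogram
#'
#' Bar chart of the signed percent errors binned to width 10, one panel per
#' model: bars left of zero are underestimates of the measured speed, bars
#' right of zero overestimates.
#'
#' @param object An `error_summary` tibble (one or more rows, e.g. from
#'   [evaluate_models()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_summary <- function(object, ...) {
  bars <- object |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::unnest("bins") |>
    dplyr::mutate(mid = (.data$lower + .data$upper) / 2)
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 9, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(gait ~ model) +
    ggplot2::labs(x = "signed percent error (%)", y = "trackways",
                  title = "Speed prediction error by model")
}
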