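#' Fit a gait-specific linear speed-stride model
#'
#' Ordinary least-squares regression of measured speed on mean stride length
#' for one gait. Fitting is always per gait, never pooled, because the slope
#' of the speed-stride relationship differs between walking, grounded
#' running and aerial running. Records lacking a ground-truth speed are
#' excluded with a message; no weighting by the number of strides averaged
#' is applied.
#'
#' Besides the \code{\link[stats]{lm}} fit, the returned object stores the
#' sufficient statistics (n, mean and centred sum of squares of the stride
#' lengths, residual SD) needed to rebuild prediction intervals, so a model
#' reloaded from the plain-text model file (see [write_gait_models()])
#' predicts identically to a freshly fitted one.
#'
#' @param data A trackway tibble (see [read_trackways()]).
#' @param gait One gait label: `walking`, `grounded_running` or
#'   `aerial_running` (alias `trot` accepted).
#' @return An object of class `gait_model` with elements `gait`, `slope`,
#'   `intercept`, `n`, `residual_sd`, `r2`, `f_stat`, `df` (a pair, `1` and
#'   `n - 2`), `l_range`, `x_mean`, `x_ssx` and (for fresh fits) `fit`, the
#'   underlying `lm` object, plus `data`, the rows used.
#' @examples
#' trk <- generate_trackways(seed = 1)
#' fit_gait_model(trk, "walking")
#' @export
fit_gait_model <- function(data, gait) {
  data <- validate_trackways(data)
  gait <- normalize_gait(gait, context = "model gait")
  if (length(gait) != 1L || is.na(gait)) abort("`gait` must be a single gait label.")
  sub <- data[!is.na(data$gait) & data$gait == gait, ]
  dropped <- sum(is.na(sub$u_measured))
  if (dropped > 0) {
    inform(paste0(dropped, " ", gait, " record(s) without u_measured excluded from fitting."))
  }
  sub <- sub[!is.na(sub$u_measured), ]
  n <- nrow(sub)
  if (n < 3L) {
    abort(paste0("Insufficient data: need at least 3 '", gait,
                 "' records with both l_stride and u_measured, got ", n, "."))
  }
  if (stats::var(sub$l_stride) == 0) {
    abort("Degenerate design: zero variance in l_stride for this gait.")
  }
  fit <- lm(u_measured ~ l_stride, data = sub)
  # noiseless calibration data are a legitimate degenerate input (handled in
  # predict/residual paths); silence only summary.lm's perfect-fit warning
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  r2 <- unname(sm$r.squared)
  new_gait_model(
    gait = gait,
    slope = unname(coef(fit)[["l_stride"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    n = n,
    residual_sd = unname(sm$sigma),
    r2 = r2,
    l_range = range(sub$l_stride),
    x_mean = mean(sub$l_stride),
    x_ssx = sum((sub$l_stride - mean(sub$l_stride))^2),
    fit = fit,
    data = sub
  )
}

new_gait_model <- function(gait, slope, intercept, n, residual_sd, r2,
                           l_range, x_mean, x_ssx, fit = NULL, data = NULL) {
  structure(
    list(
      gait = gait, slope = slope, intercept = intercept, n = as.integer(n),
      residual_sd = residual_sd, r2 = r2,
      f_stat = r2 / (1 - r2) * (n - 2),
      df = c(1L, as.integer(n) - 2L),
      l_range = l_range, x_mean = x_mean, x_ssx = x_ssx,
      fit = fit, data = data
    ),
    class = "gait_model"
  )
}

#' @export
print.gait_model <- function(x, ...) {
  cat("<gait_model> ", x$gait, "\n", sep = "")
  cat(sprintf("  U = %.3f l_stride %+.3f  (n = %d, r2 = %.3f, F[%d,%d] = %.2f)\n",
              x$slope, x$intercept, x$n, x$r2, x$df[1], x$df[2], x$f_stat))
  cat(sprintf("  residual SD %.4f m/s, stride range %.3f-%.3f m\n",
              x$residual_sd, x$l_range[1], x$l_range[2]))
  invisible(x)
}

#' Fit the speed-stride model for every gait present
#'
#' @param data A trackway tibble with gait labels and measured speeds.
#' @param gaits Gait labels to fit; defaults to every controlled-vocabulary
#'   gait present in the data.
#' @return A named list of `gait_model` objects, class `gait_model_list`.
#' @export
fit_gait_models <- function(data, gaits = NULL) {
  data <- validate_trackways(data)
  if (is.null(gaits)) {
    gaits <- intersect(gait_levels(), unique(data$gait))
  }
  if (!length(gaits)) abort("No gait labels found to fit.")
  models <- lapply(gaits, function(g) fit_gait_model(data, g))
  structure(setNames(models, gaits), class = "gait_model_list")
}

#' @export
print.gait_model_list <- function(x, ...) {
  cat("<gait_model_list> ", length(x), " gait model(s)\n", sep = "")
  for (m in x) print(m)
  invisible(x)
}

#' Point prediction with a t-based prediction interval
#'
#' Predicts speed at new stride lengths from a fitted gait model, with a
#' two-sided prediction interval for a single new observation: the interval
#' accounts for both the residual scatter and the uncertainty of the fitted
#' line at that stride length, so it widens hyperbolically away from the
#' mean of the training stride lengths. Computed from the stored sufficient
#' statistics, `se_pred = s sqrt(1 + 1/n + (l - lbar)^2 / Sxx)` with a
#' t quantile on `n - 2` degrees of freedom, which is exactly what
#' \code{\link[stats]{predict.lm}} computes for a simple regression.
#'
#' @param model A `gait_model`.
#' @param l_stride Stride length(s) in metres at which to predict.
#' @param level Coverage probability in (0, 1); default 0.95.
#' @return A tibble with columns `l_stride`, `fit`, `lwr`, `upr` (m/s).
#' @export
predict_with_interval <- function(model, l_stride, level = 0.95) {
  if (!inherits(model, "gait_model")) abort("`model` must be a fitted gait_model.")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must be a single probability strictly between 0 and 1.")
  }
  check_positive(l_stride, "l_stride")
  fit <- model$intercept + model$slope * l_stride
  se_pred <- model$residual_sd *
    sqrt(1 + 1 / model$n + (l_stride - model$x_mean)^2 / model$x_ssx)
  tq <- qt(1 - (1 - level) / 2, df = model$df[2])
  tibble::tibble(
    l_stride = l_stride,
    fit = fit,
    lwr = fit - tq * se_pred,
    upr = fit + tq * se_pred
  )
}

#' Shapiro-Wilk normality check of the fit residuals
#'
#' The prediction intervals assume Gaussian residual scatter about the
#' fitted line; this runs a Shapiro-Wilk test on the residuals of a fitted
#' gait model. Zero-variance residuals (an exact fit) make the statistic
#' undefined: that degenerate case is flagged rather than raised.
#'
#' @param model A `gait_model` fitted in this session (needs the stored
#'   residuals).
#' @return A one-row tibble: `gait`, `n`, `statistic`, `p_value`,
#'   `degenerate`.
#' @export
residual_normality <- function(model) {
  if (!inherits(model, "gait_model")) abort("`model` must be a fitted gait_model.")
  if (is.null(model$fit)) {
    abort("This gait_model was reloaded without residuals; refit to test normality.")
  }
  res <- stats::residuals(model$fit)
  if (length(res) < 3L) abort("Insufficient data: need at least 3 residuals.")
  if (sd(res) < 1e-12) {  # exact fit up to floating noise
    warn("Residuals have zero variance; Shapiro-Wilk statistic is undefined.")
    return(tibble::tibble(gait = model$gait, n = length(res),
                          statistic = NA_real_, p_value = NA_real_,
                          degenerate = TRUE))
  }
  sw <- shapiro.test(res)
  tibble::tibble(gait = model$gait, n = length(res),
                 statistic = unname(sw$statistic), p_value = sw$p.value,
                 degenerate = FALSE)
}

#' Write fitted gait models to a plain-text model file
#'
#' Serializes the per-gait coefficients and sufficient statistics as YAML
#' key-value text, reloadable by [read_gait_models()]; reloaded models
#' produce identical predictions and intervals (they lack only the stored
#' residuals, so [residual_normality()] requires a fresh fit).
#'
#' @param models A `gait_model_list` or single `gait_model`.
#' @param path Output path.
#' @return `models`, invisibly.
#' @export
write_gait_models <- function(models, path) {
  if (inherits(models, "gait_model")) {
    models <- structure(setNames(list(models), models$gait), class = "gait_model_list")
  }
  payload <- lapply(unclass(models), function(m) {
    list(gait = m$gait, slope = m$slope, intercept = m$intercept, n = m$n,
         residual_sd = m$residual_sd, r2 = m$r2,
         l_min = m$l_range[1], l_max = m$l_range[2],
         x_mean = m$x_mean, x_ssx = m$x_ssx)
  })
  yaml::write_yaml(payload, path, precision = 15L)
  invisible(models)
}

#' Reload gait models written by [write_gait_models()]
#'
#' @param path Path to the model file.
#' @return A `gait_model_list`.
#' @export
read_gait_models <- function(path) {
  if (!file.exists(path)) abort(paste0("Model file not found: ", path))
  payload <- yaml::read_yaml(path)
  models <- lapply(payload, function(m) {
    new_gait_model(
      gait = m$gait, slope = m$slope, intercept = m$intercept, n = m$n,
      residual_sd = m$residual_sd, r2 = m$r2,
      l_range = c(m$l_min, m$l_max), x_mean = m$x_mean, x_ssx = m$x_ssx
    )
  })
  structure(setNames(models, vapply(models, `[[`, "", "gait")),
            class = "gait_model_list")
}

#' @rdname fit_gait_model
#' @param x A `gait_model` (for `tidy`/`glance`).
#' @param ... Unused.
#' @export
tidy.gait_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    cf <- summary(x$fit)$coefficients
    tibble::tibble(
      gait = x$gait,
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      std.error = cf[, "Std. Error"],
      statistic = cf[, "t value"],
      p.value = cf[, "Pr(>|t|)"]
    )
  } else {
    tibble::tibble(
      gait = x$gait,
      term = c("(Intercept)", "l_stride"),
      estimate = c(x$intercept, x$slope),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    )
  }
}

#' @rdname fit_gait_model
#' @export
glance.gait_model <- function(x, ...) {
  tibble::tibble(
    gait = x$gait, n = x$n, slope = x$slope, intercept = x$intercept,
    r.squared = x$r2, f_stat = x$f_stat, df1 = x$df[1], df2 = x$df[2],
    residual_sd = x$residual_sd, l_min = x$l_range[1], l_max = x$l_range[2]
  )
}

#' @export
tidy.gait_model_list <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' @export
glance.gait_model_list <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}
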