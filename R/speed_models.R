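#' Froude number of a moving animal
#'
#' The dimensionless Froude number `Fr = U^2 / (g h)` equalises the ratio of
#' centripetal to gravitational force: geometrically similar animals moving
#' at equal `Fr` move in a dynamically similar way, which is what licenses
#' transferring gait and speed relationships across body sizes.
#'
#' @param u Speed in m/s (vectorized). Must be non-negative.
#' @param profile A [species_profile()] supplying `h` and `g`.
#' @return Numeric vector of Froude numbers.
#' @examples
#' froude(0.92, species_profile())  # ~0.5, a fast-walking ptarmigan
#' @export
froude <- function(u, profile = species_profile()) {
  profile <- as_profile(profile)
  if (any(u < 0, na.rm = TRUE)) abort("`u` must be non-negative (m/s).")
  u^2 / (profile$g * profile$h)
}

#' Relative stride length
#'
#' Stride length divided by hip height, `lambda = l_stride / h`: the
#' dimensionless stride used to diagnose gait from trackways alone.
#'
#' @param l_stride Stride length in metres (vectorized). Must be positive.
#' @inheritParams froude
#' @return Numeric vector of relative stride lengths.
#' @examples
#' relative_stride(0.35, species_profile())  # ~2.03
#' @export
relative_stride <- function(l_stride, profile = species_profile()) {
  profile <- as_profile(profile)
  check_positive(l_stride, "l_stride")
  l_stride / profile$h
}

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    abort(paste0("`", name, "` must be positive and finite."))
  }
  invisible(x)
}

#' Alexander's walking-speed predictor
#'
#' The classic dynamic-similarity estimate of forward speed from stride
#' length and hip height, `U = 0.25 g^0.5 l_stride^1.67 h^-1.17`, derived
#' empirically across mammals and birds. It is intended for walking gaits
#' (relative stride below about 2).
#'
#' @inheritParams relative_stride
#' @return Predicted speed in m/s.
#' @examples
#' alexander_speed(0.35, species_profile())  # ~1.06 m/s
#' @export
alexander_speed <- function(l_stride, profile = species_profile()) {
  profile <- as_profile(profile)
  check_positive(l_stride, "l_stride")
  0.25 * sqrt(profile$g) * l_stride^1.67 * profile$h^-1.17
}

#' Thulborn-Wade fast-gait speed predictor
#'
#' `U = sqrt( g h (l_stride / (1.8 h))^2.56 )`, advocated for high-speed
#' gaits where the relative stride exceeds 2.9. At `l_stride = 1.8 h` it
#' reduces exactly to `sqrt(g h)` (Froude number 1).
#'
#' @inheritParams relative_stride
#' @return Predicted speed in m/s.
#' @examples
#' thulborn_wade_speed(0.35, species_profile())  # ~1.51 m/s
#' @export
thulborn_wade_speed <- function(l_stride, profile = species_profile()) {
  profile <- as_profile(profile)
  check_positive(l_stride, "l_stride")
  sqrt(profile$g * profile$h * (l_stride / (1.8 * profile$h))^2.56)
}

#' Trotting-speed estimate: mean of the two general predictors
#'
#' For the intermediate (trotting) band, speed is better estimated by the
#' arithmetic mean of [alexander_speed()] and [thulborn_wade_speed()] at the
#' same stride length.
#'
#' @inheritParams relative_stride
#' @return Predicted speed in m/s.
#' @export
trot_speed <- function(l_stride, profile = species_profile()) {
  (alexander_speed(l_stride, profile) + thulborn_wade_speed(l_stride, profile)) / 2
}

#' Piecewise Froude-model speed with its gait band
#'
#' Dispatches on relative stride length `lambda = l_stride / h`:
#' `lambda < 2` uses the Alexander walking predictor (walking band);
#' `2 <= lambda < 2.9` uses the mean-of-two trotting rule (trotting band);
#' `lambda >= 2.9` uses the Thulborn-Wade predictor (running band). Boundary
#' points belong to the faster band (the gait has shifted once the threshold
#' is reached). No smoothing is applied at the thresholds, so the predicted
#' speed is discontinuous there by construction.
#'
#' @inheritParams relative_stride
#' @param thresholds Increasing numeric pair `c(walk_trot, trot_run)` of
#'   relative-stride thresholds; defaults `c(2.0, 2.9)` from the comparative
#'   literature.
#' @return A tibble with columns `l_stride`, `lambda`, `band` (one of
#'   `walking`, `trotting`, `running`) and `u` (predicted speed, m/s).
#' @examples
#' froude_model_speed(c(0.30, 0.40, 0.55), species_profile())
#' @export
froude_model_speed <- function(l_stride, profile = species_profile(),
                               thresholds = c(walk_trot = 2.0, trot_run = 2.9)) {
  profile <- as_profile(profile)
  check_thresholds(thresholds)
  lambda <- relative_stride(l_stride, profile)
  band <- band_from_lambda(lambda, thresholds)
  u <- dplyr::case_when(
    band == "walking" ~ alexander_speed(l_stride, profile),
    band == "trotting" ~ trot_speed(l_stride, profile),
    TRUE ~ thulborn_wade_speed(l_stride, profile)
  )
  tibble::tibble(l_stride = l_stride, lambda = lambda, band = band, u = u)
}

check_thresholds <- function(thresholds) {
  if (length(thresholds) != 2L || !is.numeric(thresholds) ||
      !all(is.finite(thresholds)) || thresholds[1] >= thresholds[2]) {
    abort("`thresholds` must be an increasing numeric pair c(walk_trot, trot_run).")
  }
  invisible(thresholds)
}

band_from_lambda <- function(lambda, thresholds = c(2.0, 2.9)) {
  dplyr::case_when(
    lambda < thresholds[1] ~ "walking",
    lambda < thresholds[2] ~ "trotting",
    TRUE ~ "running"
  )
}

#' Hip height from footprint length
#'
#' When the trackmaker cannot be measured, functional hip height is commonly
#' proxied as a multiple of foot length — conventionally four times. Postural
#' estimates obtained this way can be off by a factor of 1.5 or more, which
#' propagates directly into every Froude-based speed estimate.
#'
#' @param foot_length Foot (footprint) length in metres. Must be positive.
#' @param factor Multiplier, default 4. Must be positive.
#' @return Estimated hip height in metres.
#' @examples
#' hip_from_footlength(0.0432)  # ~0.173 m
#' @export
hip_from_footlength <- function(foot_length, factor = 4) {
  check_positive(foot_length, "foot_length")
  check_positive(factor, "factor")
  factor * foot_length
}

#' Predict speeds for a trackway table under one or more models
#'
#' The pipeline verb tying the predictors together: for each trackway and
#' each requested model it produces a point speed prediction, a prediction
#' interval where the model supports one (the species-specific calibrated
#' models), the gait the prediction used, and the signed percent error
#' whenever a ground-truth speed is present.
#'
#' Models:
#' \describe{
#'   \item{`species`}{gait-wise calibrated linear models; requires
#'     `gait_models` and a `gait` label on each record.}
#'   \item{`alexander`}{the walking predictor applied to every record.}
#'   \item{`thulborn_wade`}{the fast-gait predictor applied to every record.}
#'   \item{`froude_piecewise`}{threshold dispatch on relative stride.}
#' }
#'
#' @param data A trackway tibble (see [read_trackways()]).
#' @param profile A [species_profile()]; needed by all Froude-based models.
#' @param gait_models A named list of fitted gait models from
#'   [fit_gait_models()]; needed by the `species` model.
#' @param models Character vector of model names to run.
#' @param level Prediction-interval coverage for the species model.
#' @return A tibble with one row per (trackway, model): `id`, `l_stride`,
#'   `gait`, `model`, `u_pred`, `u_lwr`, `u_upr` (NA for closed-form models),
#'   `u_measured` and `pct_error`.
#' @export
predict_speeds <- function(data, profile = species_profile(),
                           gait_models = NULL,
                           models = c("species", "alexander",
                                      "thulborn_wade", "froude_piecewise"),
                           level = 0.95) {
  data <- validate_trackways(data)
  models <- match.arg(models, several.ok = TRUE)
  profile <- as_profile(profile)

  one_model <- function(model) {
    out <- data[c("id", "l_stride", "gait", "u_measured")]
    out$model <- model
    out$u_lwr <- NA_real_
    out$u_upr <- NA_real_
    if (model == "species") {
      if (is.null(gait_models)) {
        abort("The 'species' model needs `gait_models` from fit_gait_models().")
      }
      if (anyNA(out$gait)) {
        abort("The 'species' model needs a gait label on every record.")
      }
      missing_models <- setdiff(unique(out$gait), names(gait_models))
      if (length(missing_models)) {
        abort(paste0("No fitted model for gait(s): ",
                     paste(missing_models, collapse = ", ")))
      }
      pred <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
        predict_with_interval(gait_models[[out$gait[i]]], out$l_stride[i], level)
      })
      out$u_pred <- pred$fit
      out$u_lwr <- pred$lwr
      out$u_upr <- pred$upr
    } else if (model == "alexander") {
      out$u_pred <- alexander_speed(out$l_stride, profile)
    } else if (model == "thulborn_wade") {
      out$u_pred <- thulborn_wade_speed(out$l_stride, profile)
    } else {
      fp <- froude_model_speed(out$l_stride, profile)
      out$u_pred <- fp$u
      out$gait <- fp$band
    }
    out$pct_error <- percent_error(out$u_pred, out$u_measured)
    out[c("id", "l_stride", "gait", "model", "u_pred", "u_lwr", "u_upr",
          "u_measured", "pct_error")]
  }

  dplyr::bind_rows(lapply(models, one_model))
}
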