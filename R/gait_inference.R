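#' Classify gait from relative stride length thresholds
#'
#' Assigns each trackway a single gait band from its dimensionless relative
#' stride `lambda = l_stride / h`, using the comparative-literature
#' thresholds: walking below 2.0, a bouncing (trotting) gait from 2.0, and
#' running from 2.9. Boundary points belong to the faster gait — once the
#' threshold is reached the gait has shifted. This method is never
#' ambiguous by construction; its weakness is that the thresholds are
#' cross-species generalisations that a given species need not respect.
#'
#' @param data A trackway tibble (see [read_trackways()]).
#' @param profile A [species_profile()] supplying hip height.
#' @param thresholds Increasing pair `c(walk_trot, trot_run)`, default
#'   `c(2.0, 2.9)`.
#' @return A tibble with one row per trackway: `id`, `l_stride`, `lambda`,
#'   `method` (`"relative_stride"`), `gait_call`, `gaits` (list column),
#'   `ambiguous` (always `FALSE`).
#' @examples
#' trk <- generate_trackways(seed = 1)
#' classify_relative_stride(trk, species_profile())
#' @export
classify_relative_stride <- function(data, profile = species_profile(),
                                     thresholds = c(walk_trot = 2.0, trot_run = 2.9)) {
  data <- validate_trackways(data)
  profile <- as_profile(profile)
  check_thresholds(thresholds)
  lambda <- relative_stride(data$l_stride, profile)
  call <- band_from_lambda(lambda, thresholds)
  tibble::tibble(
    id = data$id,
    l_stride = data$l_stride,
    lambda = lambda,
    method = "relative_stride",
    gait_call = call,
    gaits = as.list(call),
    ambiguous = FALSE
  )
}

#' Classify gait from calibrated species stride ranges
#'
#' Assigns each trackway every gait whose observed (calibration) stride
#' range contains its stride length. Because a species' gaits overlap in
#' stride length while transitioning, a stride may sit inside two ranges at
#' once: such trackways are flagged `ambiguous` — from the trackway alone
#' their gait (and hence speed) cannot be determined. A stride outside every
#' range is assigned the nearest range and flagged `out_of_range`, never
#' silently clamped.
#'
#' With `use = "speed_interval"`, a matching pair of gaits is only counted
#' as ambiguous when, additionally, their speed prediction intervals at that
#' stride length overlap — a stricter reading of "cannot be assigned a gait
#' and speed".
#'
#' @param data A trackway tibble.
#' @param models A `gait_model_list` from [fit_gait_models()].
#' @param use `"stride_range"` (default) or `"speed_interval"`.
#' @param level Prediction-interval level for `use = "speed_interval"`.
#' @return A tibble with one row per trackway: `id`, `l_stride`, `method`,
#'   `gait_call` (matching gaits joined with `/`), `gaits` (list column of
#'   matching labels), `n_matches`, `ambiguous`, `out_of_range`.
#' @export
classify_species_ranges <- function(data, models,
                                    use = c("stride_range", "speed_interval"),
                                    level = 0.95) {
  data <- validate_trackways(data)
  use <- match.arg(use)
  if (!inherits(models, "gait_model_list") || !length(models)) {
    abort("`models` must be a non-empty gait_model_list from fit_gait_models().")
  }
  ranges <- glance(models)

  classify_one <- function(l) {
    inside <- ranges$l_min <= l & l <= ranges$l_max
    out_of_range <- !any(inside)
    if (out_of_range) {
      dist <- pmax(ranges$l_min - l, l - ranges$l_max, 0)
      matches <- ranges$gait[which.min(dist)]
    } else {
      matches <- ranges$gait[inside]
    }
    ambiguous <- length(matches) > 1L
    if (ambiguous && use == "speed_interval") {
      pis <- purrr::map_dfr(matches, function(g) predict_with_interval(models[[g]], l, level))
      # overlapping PIs of any pair keep the ambiguity; disjoint PIs resolve it
      any_overlap <- FALSE
      for (i in seq_len(nrow(pis) - 1L)) {
        for (j in seq(i + 1L, nrow(pis))) {
          if (pis$lwr[i] <= pis$upr[j] && pis$lwr[j] <= pis$upr[i]) any_overlap <- TRUE
        }
      }
      if (!any_overlap) {
        mid <- (ranges$l_min[match(matches, ranges$gait)] +
                  ranges$l_max[match(matches, ranges$gait)]) / 2
        matches <- matches[which.min(abs(l - mid))]
        ambiguous <- FALSE
      }
    }
    list(matches = matches, ambiguous = ambiguous, out_of_range = out_of_range)
  }

  res <- lapply(data$l_stride, classify_one)
  tibble::tibble(
    id = data$id,
    l_stride = data$l_stride,
    method = "species_ranges",
    gait_call = vapply(res, function(r) paste(r$matches, collapse = "/"), ""),
    gaits = lapply(res, `[[`, "matches"),
    n_matches = vapply(res, function(r) length(r$matches), 1L),
    ambiguous = vapply(res, `[[`, TRUE, "ambiguous"),
    out_of_range = vapply(res, `[[`, TRUE, "out_of_range")
  )
}

#' Fraction of trackways that cannot be assigned a single gait
#'
#' The proportion of trackways whose [classify_species_ranges()] call is
#' ambiguous: their stride length falls inside the observed stride range of
#' more than one calibrated gait, so gait — and therefore speed — cannot be
#' inferred from the trackway alone.
#'
#' @inheritParams classify_species_ranges
#' @return A single proportion in \[0, 1\].
#' @export
unclassifiable_fraction <- function(data, models,
                                    use = c("stride_range", "speed_interval"),
                                    level = 0.95) {
  data <- validate_trackways(data)
  if (!nrow(data)) abort("Cannot compute an unclassifiable fraction of zero trackways.")
  mean(classify_species_ranges(data, models, use = use, level = level)$ambiguous)
}
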