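#' Default gait generator specifications
#'
#' The three gait-wise generating truths used throughout the package's
#' simulations, emulating the structure of a matched trackway/video study of
#' Svalbard rock ptarmigan moving over snow:
#'
#' * linear speed-stride relations `U = 3.20 l - 0.23` (walking),
#'   `U = 2.34 l + 0.34` (grounded running), `U = 4.29 l - 0.03` (aerial
#'   running), in m/s per m;
#' * Gaussian residual SDs 0.092, 0.168 and 0.180 m/s, back-calculated as
#'   the published prediction-interval half-widths divided by 1.96 — an
#'   acknowledged approximation, since a prediction-interval half-width
#'   slightly exceeds 1.96 residual SDs;
#' * stride-length ranges 0.225-0.322, 0.312-0.436 and 0.373-0.646 m,
#'   obtained by inverting the published predicted-speed endpoints through
#'   each gait's own equation (forward substitution recovers the published
#'   speed ranges);
#' * sample sizes n = 48, 56 and 61.
#'
#' Note the ranges overlap where gaits transition (walking/grounded around
#' 0.31-0.32 m, grounded/aerial around 0.37-0.44 m): that overlap is what
#' makes some trackways unclassifiable from stride length alone.
#'
#' @return A tibble with one row per gait: `gait`, `slope`, `intercept`,
#'   `residual_sd`, `l_min`, `l_max`, `n`, `stride_distribution`
#'   (`"uniform"` by default; `"truncated_normal"` also supported).
#' @export
default_gait_specs <- function() {
  tibble::tibble(
    gait = gait_levels(),
    slope = c(3.20, 2.34, 4.29),
    intercept = c(-0.23, 0.34, -0.03),
    residual_sd = c(0.092, 0.168, 0.180),
    l_min = c(0.225, 0.312, 0.373),
    l_max = c(0.322, 0.436, 0.646),
    n = c(48L, 56L, 61L),
    stride_distribution = "uniform"
  )
}

validate_gait_specs <- function(specs) {
  specs <- tibble::as_tibble(specs)
  needed <- c("gait", "slope", "intercept", "residual_sd", "l_min", "l_max", "n")
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols)) {
    abort(paste0("Generator spec missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"stride_distribution" %in% names(specs)) specs$stride_distribution <- "uniform"
  if (any(!specs$stride_distribution %in% c("uniform", "truncated_normal"))) {
    abort("`stride_distribution` must be 'uniform' or 'truncated_normal'.")
  }
  if (any(specs$l_min >= specs$l_max)) abort("Each spec needs l_min < l_max.")
  if (any(specs$residual_sd < 0)) abort("`residual_sd` must be non-negative.")
  if (any(specs$n < 1L)) abort("Each spec needs n >= 1.")
  specs
}

# Independent 32-bit substream seed for one gait: adding or removing a gait
# spec must not reshuffle the draws of the others, so each gait's stream is
# keyed on (seed, gait label, purpose) rather than on draw order.
substream_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- (sum(codes * seq_along(codes)) * 2654435761) %% 2147483647
  as.integer((as.numeric(seed) * 69621 + h) %% 2147483647)
}

draw_strides <- function(n, l_min, l_max, distribution) {
  if (distribution == "uniform") {
    runif(n, l_min, l_max)
  } else {
    # inverse-CDF truncated normal centred mid-range, SD = range/4
    m <- (l_min + l_max) / 2
    s <- (l_max - l_min) / 4
    p <- runif(n, stats::pnorm(l_min, m, s), stats::pnorm(l_max, m, s))
    qnorm(p, m, s)
  }
}

generate_one_gait <- function(spec, seed, measurement_sd, purpose, n = spec$n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, paste0(spec$gait, "::", purpose)))
  l_true <- draw_strides(n, spec$l_min, spec$l_max, spec$stride_distribution)
  u <- spec$slope * l_true + spec$intercept + rnorm(n, 0, spec$residual_sd)
  l_rec <- l_true + rnorm(n, 0, measurement_sd)
  tibble::tibble(
    id = sprintf("%s_%s_%03d", substr(purpose, 1, 1), abbreviate_gait(spec$gait), seq_len(n)),
    l_stride = l_rec,
    n_strides = sample(1:5, n, replace = TRUE),
    gait = spec$gait,
    u_measured = u
  )
}

abbreviate_gait <- function(gait) {
  c(walking = "walk", grounded_running = "grun", aerial_running = "arun")[gait]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic matched trackway/video dataset
#'
#' For each gait spec, draws `n` true stride lengths from the spec's stride
#' distribution over its range, sets the video-measured speed to
#' `slope * l + intercept + N(0, residual_sd)`, and then perturbs the
#' *recorded* stride length by `N(0, measurement_sd)` to mimic measuring a
#' photographed trackway (the speed was produced by the true stride, the
#' analyst only sees the measured one). Deterministic given `seed`; each
#' gait draws from its own substream, so adding a gait spec does not
#' reshuffle the others.
#'
#' @param specs A gait spec tibble; defaults to [default_gait_specs()].
#' @param seed Integer seed.
#' @param measurement_sd SD (m) of the stride measurement error; default 0.
#' @return A trackway tibble (schema of [read_trackways()]) with
#'   `sum(specs$n)` rows, every record carrying gait and measured speed.
#' @examples
#' trk <- generate_trackways(seed = 42)
#' dplyr::count(trk, gait)
#' @export
generate_trackways <- function(specs = default_gait_specs(), seed = 1L,
                               measurement_sd = 0) {
  specs <- validate_gait_specs(specs)
  if (measurement_sd < 0) abort("`measurement_sd` must be non-negative.")
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    generate_one_gait(specs[i, ], seed, measurement_sd, purpose = "train")
  })
  validate_trackways(dplyr::bind_rows(rows))
}

#' Generate a hold-out set of ground-truthed trackways
#'
#' Draws `size` trackways with gait membership multinomial with
#' probabilities proportional to the specs' sample sizes (so the hold-out
#' mirrors the gait mix of the calibration data), then generates each
#' record from its gait's spec exactly as [generate_trackways()] does.
#' Every record keeps its gait label and measured speed for ground truth.
#'
#' @inheritParams generate_trackways
#' @param size Number of hold-out trackways, default 50.
#' @return A trackway tibble with `size` rows.
#' @export
generate_holdout <- function(specs = default_gait_specs(), seed = 1L,
                             size = 50L, measurement_sd = 0) {
  specs <- validate_gait_specs(specs)
  if (size < 1L) abort("`size` must be at least 1.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, "holdout::mix"))
  counts <- as.vector(rmultinom(1, size, prob = specs$n))
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    if (counts[i] == 0L) return(NULL)
    generate_one_gait(specs[i, ], seed, measurement_sd,
                      purpose = "holdout", n = counts[i])
  })
  validate_trackways(dplyr::bind_rows(rows))
}
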