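#' Species profile: hip height and gravity
#'
#' Bundles the per-species constants every speed predictor needs: the
#' functional hip height `h` (metres, the height of the hip above the ground
#' in normal stance — proxied as four times foot length when the animal
#' cannot be measured, see [hip_from_footlength()]) and the gravitational
#' acceleration `g`. Defaults describe a male Svalbard rock ptarmigan
#' (*Lagopus muta hyperborea*), hip height 172.7 mm.
#'
#' @param species Species identifier (free text).
#' @param h Functional hip height in metres. Must be positive.
#' @param g Gravitational acceleration in m/s^2. Must be positive.
#'
#' @return An object of class `species_profile`: a named list with elements
#'   `species`, `h` and `g`.
#' @examples
#' ptarmigan <- species_profile()
#' ptarmigan$h
#' @export
species_profile <- function(species = "Lagopus muta hyperborea",
                            h = 0.1727, g = 9.81) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    abort("`h` (hip height, m) must be a single positive number.")
  }
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0) {
    abort("`g` (gravitational acceleration, m/s^2) must be a single positive number.")
  }
  structure(
    list(species = as.character(species)[1L], h = as.numeric(h), g = as.numeric(g)),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile> ", x$species, "\n", sep = "")
  cat("  hip height h = ", format(x$h), " m, g = ", format(x$g), " m/s^2\n", sep = "")
  invisible(x)
}

#' Read a species profile from a key-value config file
#'
#' The file is YAML (which subsumes plain `key: value` text) with keys
#' `species`, `h` and `g`; missing keys fall back to the
#' [species_profile()] defaults.
#'
#' @param path Path to the config file.
#' @return A `species_profile`.
#' @export
read_species_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("Species profile file not found: ", path))
  cfg <- yaml::read_yaml(path)
  defaults <- species_profile()
  species_profile(
    species = cfg$species %||% defaults$species,
    h = cfg$h %||% defaults$h,
    g = cfg$g %||% defaults$g
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_profile <- function(profile) {
  if (inherits(profile, "species_profile")) return(profile)
  if (is.list(profile) && all(c("h", "g") %in% names(profile))) {
    return(species_profile(profile$species %||% "unknown", profile$h, profile$g))
  }
  abort("`profile` must be a species_profile (see species_profile()).")
}

# Normalize a gait label vector: blank -> NA, "trot" is accepted as an input
# alias for the intermediate bouncing gait and mapped onto grounded running.
normalize_gait <- function(gait, context = "gait") {
  gait <- as.character(gait)
  gait[!is.na(gait) & trimws(gait) == ""] <- NA_character_
  gait <- trimws(gait)
  is_trot <- !is.na(gait) & gait %in% c("trot", "trotting")
  if (any(is_trot)) {
    inform(paste0(
      sum(is_trot), " '", unique(gait[is_trot])[1], "' label(s) normalized to ",
      "'grounded_running' (the intermediate bouncing gait of this species)."
    ))
    gait[is_trot] <- "grounded_running"
  }
  bad <- !is.na(gait) & !gait %in% gait_levels()
  if (any(bad)) {
    abort(paste0(
      "Unknown ", context, " label(s): ",
      paste(unique(gait[bad]), collapse = ", "),
      ". Allowed labels: ", paste(gait_levels(), collapse = ", "),
      " (plus alias 'trot' for grounded_running)."
    ))
  }
  gait
}

parse_numeric_column <- function(x, column) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    abort(paste0(
      "Malformed numeric value in column '", column, "', data row(s) ",
      paste(bad, collapse = ", "), ": ",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  out
}

#' Read a trackway CSV
#'
#' Reads a matched trackway/video dataset: one row per trackway with its mean
#' stride length, the number of strides the mean was taken over, and — when
#' the trackway was ground-truthed — the gait observed on video and the speed
#' measured from it. Units are fixed to metres and m/s; no unit detection is
#' attempted. The whole file is validated before anything is returned: a
#' malformed numeric cell or an unknown gait label is an error naming the row
#' and column, so no row is ever silently dropped.
#'
#' Expected header: `id,l_stride,n_strides,gait,u_measured`; the last three
#' columns are optional and blank cells parse as missing. `"trot"` is
#' accepted as a gait alias and normalized to `grounded_running` with a
#' message.
#'
#' @param path Path to the CSV file (comma-separated, UTF-8, `.` decimal
#'   mark, header mandatory).
#' @return A tibble with columns `id` (character), `l_stride` (m),
#'   `n_strides` (integer, `NA` when absent), `gait` (character or `NA`) and
#'   `u_measured` (m/s or `NA`).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,l_stride,n_strides,gait,u_measured",
#'              "t1,0.35,3,walking,0.92"), tf)
#' read_trackways(tf)
#' @export
read_trackways <- function(path) {
  if (!file.exists(path)) abort(paste0("Trackway file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("id", "l_stride")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(raw)
  out <- tibble::tibble(
    id = as.character(raw$id),
    l_stride = parse_numeric_column(raw$l_stride, "l_stride"),
    n_strides = if ("n_strides" %in% names(raw)) {
      as.integer(parse_numeric_column(raw$n_strides, "n_strides"))
    } else rep(NA_integer_, n),
    gait = if ("gait" %in% names(raw)) normalize_gait(raw$gait) else rep(NA_character_, n),
    u_measured = if ("u_measured" %in% names(raw)) {
      parse_numeric_column(raw$u_measured, "u_measured")
    } else rep(NA_real_, n)
  )
  validate_trackways(out)
}

#' Validate a trackway table
#'
#' Enforces the record invariants: positive stride lengths, positive measured
#' speeds where present, and a stride count between 1 and 5 (a count above 5
#' is only a warning — the protocol measured the mean of 1 to 5 strides, but
#' more strides are not wrong, just unexpected).
#'
#' @param data A data frame with at least `id` and `l_stride`.
#' @return The validated data as a tibble (gait labels normalized).
#' @export
validate_trackways <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("id", "l_stride") %in% names(data))) {
    abort("Trackway data needs at least columns `id` and `l_stride`.")
  }
  if (!"n_strides" %in% names(data)) data$n_strides <- NA_integer_
  if (!"gait" %in% names(data)) data$gait <- NA_character_
  if (!"u_measured" %in% names(data)) data$u_measured <- NA_real_
  data$gait <- normalize_gait(data$gait)

  bad_l <- which(is.na(data$l_stride) | data$l_stride <= 0)
  if (length(bad_l)) {
    abort(paste0("`l_stride` must be a positive length (m); offending row(s): ",
                 paste(bad_l, collapse = ", ")))
  }
  bad_u <- which(!is.na(data$u_measured) & data$u_measured <= 0)
  if (length(bad_u)) {
    abort(paste0("`u_measured`, when present, must be positive (m/s); row(s): ",
                 paste(bad_u, collapse = ", ")))
  }
  bad_ns <- which(!is.na(data$n_strides) & data$n_strides < 1L)
  if (length(bad_ns)) {
    abort(paste0("`n_strides` must be at least 1; row(s): ",
                 paste(bad_ns, collapse = ", ")))
  }
  high_ns <- which(!is.na(data$n_strides) & data$n_strides > 5L)
  if (length(high_ns)) {
    warn(paste0("`n_strides` above 5 in row(s) ", paste(high_ns, collapse = ", "),
                "; the measurement protocol expects means of 1-5 strides."))
  }
  data[c("id", "l_stride", "n_strides", "gait", "u_measured")]
}

#' Write a trackway table to CSV
#'
#' Writes the standard schema (`id,l_stride,n_strides,gait,u_measured`) with
#' full numeric precision so a write/read round trip reproduces every value.
#'
#' @param data A trackway tibble (see [read_trackways()]).
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_trackways <- function(data, path) {
  data <- validate_trackways(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Write per-trackway, per-model predictions to CSV
#'
#' One row per (trackway, model) pair: the point prediction, the prediction
#' interval where the model provides one, the gait used, and the signed
#' percent error where a ground-truth speed was available. Numbers are
#' written at full precision; a round trip through [readr::read_csv()]
#' reproduces them well within 6 significant figures.
#'
#' @param data A predictions tibble, typically from [predict_speeds()]. Must
#'   contain `id` and `model`.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_predictions <- function(data, path) {
  data <- tibble::as_tibble(data)
  if (!all(c("id", "model") %in% names(data))) {
    abort("Prediction data needs at least columns `id` and `model`.")
  }
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
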