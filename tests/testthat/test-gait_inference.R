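test_that("relative-stride thresholds classify the worked examples", {
  trk <- tibble::tibble(id = c("slow", "fastwalk", "boundary"),
                        l_stride = c(0.30, 0.35, 2.9 * 0.1727))
  res <- classify_relative_stride(trk, ptarmigan)
  expect_equal(res$lambda[1], 0.30 / 0.1727, tolerance = 1e-12)
  expect_equal(res$gait_call, c("walking", "trotting", "running"))
  expect_false(any(res$ambiguous))
  expect_error(
    classify_relative_stride(trk, ptarmigan, thresholds = c(2.9, 2.0)),
    "increasing")
})

test_that("relative-stride labels are piecewise constant and ordered in stride", {
  trk <- tibble::tibble(id = as.character(1:300),
                        l_stride = seq(0.05, 1.0, length.out = 300))
  calls <- classify_relative_stride(trk, ptarmigan)$gait_call
  idx <- match(calls, c("walking", "trotting", "running"))
  expect_true(all(diff(idx) >= 0))
  expect_setequal(unique(calls), c("walking", "trotting", "running"))
})

test_that("species-range classification flags overlap ambiguity and out-of-range strides", {
  models <- structure(
    list(walking = range_model("walking", 0.20, 0.30),
         grounded_running = range_model("grounded_running", 0.28, 0.40)),
    class = "gait_model_list")
  trk <- tibble::tibble(id = c("a", "b", "c"), l_stride = c(0.25, 0.29, 0.55))
  res <- classify_species_ranges(trk, models)
  expect_equal(res$gait_call, c("walking", "walking/grounded_running",
                                "grounded_running"))
  expect_equal(res$ambiguous, c(FALSE, TRUE, FALSE))
  expect_equal(res$out_of_range, c(FALSE, FALSE, TRUE))
  expect_equal(res$n_matches, c(1L, 2L, 1L))
})

test_that("unclassifiable fraction equals the enumeration oracle", {
  trk <- generate_trackways(seed = 21)
  models <- fit_gait_models(trk)
  res <- classify_species_ranges(trk, models)
  # brute-force enumeration against the glance ranges
  gl <- glance(models)
  manual <- vapply(trk$l_stride, function(l) {
    sum(gl$l_min <= l & l <= gl$l_max) > 1L
  }, TRUE)
  expect_equal(res$ambiguous, manual)
  expect_equal(unclassifiable_fraction(trk, models), mean(manual))
})

test_that("disjoint ranges give fraction 0 and nested intersections give 1", {
  disjoint <- structure(
    list(walking = range_model("walking", 0.20, 0.28),
         aerial_running = range_model("aerial_running", 0.40, 0.60)),
    class = "gait_model_list")
  trk <- tibble::tibble(id = c("a", "b"), l_stride = c(0.25, 0.50))
  expect_equal(unclassifiable_fraction(trk, disjoint), 0)

  overlapping <- structure(
    list(walking = range_model("walking", 0.20, 0.40),
         grounded_running = range_model("grounded_running", 0.25, 0.45)),
    class = "gait_model_list")
  inside <- tibble::tibble(id = c("a", "b"), l_stride = c(0.30, 0.35))
  expect_equal(unclassifiable_fraction(inside, overlapping), 1)
  expect_error(unclassifiable_fraction(inside[0, ], overlapping), "zero")
})

test_that("study-scale ambiguity matches the analytic overlap mass of the stride distributions", {
  # With uniform strides on the default ranges, the expected ambiguous
  # fraction is the n-weighted mass falling in the pairwise overlap
  # intervals [0.312, 0.322] and [0.373, 0.436]:
  specs <- default_gait_specs()
  p_overlap <- c(
    (0.322 - 0.312) / (0.322 - 0.225),
    ((0.322 - 0.312) + (0.436 - 0.373)) / (0.436 - 0.312),
    (0.436 - 0.373) / (0.646 - 0.373)
  )
  analytic <- sum(specs$n * p_overlap) / sum(specs$n)  # ~0.315
  models <- structure(
    setNames(lapply(seq_len(3), function(i) {
      range_model(specs$gait[i], specs$l_min[i], specs$l_max[i],
                  specs$slope[i], specs$intercept[i])
    }), specs$gait),
    class = "gait_model_list")
  big <- specs
  big$n <- big$n * 20L
  cohort <- generate_trackways(big, seed = 77)
  frac <- unclassifiable_fraction(cohort, models)
  expect_equal(frac, analytic, tolerance = 0.04 / analytic)
})

test_that("speed-interval mode only keeps ambiguity when prediction intervals overlap", {
  trk <- generate_trackways(seed = 13)
  models <- fit_gait_models(trk)
  stride_mode <- classify_species_ranges(trk, models, use = "stride_range")
  speed_mode <- classify_species_ranges(trk, models, use = "speed_interval")
  # the stricter criterion can only resolve ambiguity, never create it
  expect_true(all(speed_mode$ambiguous <= stride_mode$ambiguous))
})
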