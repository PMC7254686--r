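test_that("noiseless data on the walking line is recovered exactly", {
  trk <- exact_trackways(seq(0.23, 0.32, length.out = 10), 3.20, -0.23, "walking")
  m <- fit_gait_model(trk, "walking")
  expect_equal(m$slope, 3.20, tolerance = 1e-10)
  expect_equal(m$intercept, -0.23, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-9)
  expect_equal(m$l_range, c(0.23, 0.32))
})

test_that("OLS coefficients agree with the normal-equation oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    x <- runif(n, 0.2, 0.7)
    y <- 2.5 * x + 0.1 + rnorm(n, 0, 0.2)
    trk <- tibble::tibble(id = as.character(seq_len(n)), l_stride = x,
                          n_strides = 1L, gait = "walking", u_measured = abs(y) + 0.01)
    m <- fit_gait_model(trk, "walking")
    oracle <- ols_normal_equations(trk$l_stride, trk$u_measured)
    expect_equal(m$slope, unname(oracle["slope"]), tolerance = 1e-8)
    expect_equal(m$intercept, unname(oracle["intercept"]), tolerance = 1e-8)
  }
})

test_that("sample-size bookkeeping and the F identity hold", {
  trk <- generate_trackways(seed = 3)
  m <- fit_gait_model(trk, "walking")
  expect_equal(m$n, 48L)
  expect_equal(m$df, c(1L, 46L))
  expect_equal(m$f_stat, m$r2 / (1 - m$r2) * (m$n - 2), tolerance = 1e-10)
  # independent route: the F statistic reported by summary.lm
  expect_equal(m$f_stat, unname(summary(m$fit)$fstatistic["value"]),
               tolerance = 1e-8)
})

test_that("insufficient or degenerate calibration data raises informative errors", {
  few <- exact_trackways(c(0.25, 0.30), 3.2, -0.23, "walking")
  expect_error(fit_gait_model(few, "walking"), "at least 3")
  flat <- exact_trackways(rep(0.3, 5), 3.2, -0.23, "walking")
  expect_error(fit_gait_model(flat, "walking"), "[Dd]egenerate")
  trk <- exact_trackways(seq(0.23, 0.32, length.out = 6), 3.2, -0.23, "walking")
  trk$u_measured[5:6] <- NA
  expect_message(m <- fit_gait_model(trk, "walking"), "excluded")
  expect_equal(m$n, 4L)
})

test_that("prediction intervals match predict.lm and widen away from the stride mean", {
  trk <- generate_trackways(seed = 5)
  m <- fit_gait_model(trk, "grounded_running")
  l_new <- c(0.31, 0.37, 0.43, 0.50)
  for (level in c(0.8, 0.95, 0.99)) {
    pi <- predict_with_interval(m, l_new, level = level)
    oracle <- stats::predict(m$fit, newdata = data.frame(l_stride = l_new),
                             interval = "prediction", level = level)
    expect_equal(pi$fit, unname(oracle[, "fit"]), tolerance = 1e-10)
    expect_equal(pi$lwr, unname(oracle[, "lwr"]), tolerance = 1e-10)
    expect_equal(pi$upr, unname(oracle[, "upr"]), tolerance = 1e-10)
  }
  # hyperbolic shape: width grows with distance from the training mean
  d <- c(0.001, 0.05, 0.1, 0.2)
  w <- predict_with_interval(m, m$x_mean + d)$upr -
    predict_with_interval(m, m$x_mean + d)$lwr
  expect_true(all(diff(w) > 0))
})

test_that("a zero-noise fit gives a zero-width interval", {
  trk <- exact_trackways(seq(0.23, 0.32, length.out = 8), 3.2, -0.23, "walking")
  m <- fit_gait_model(trk, "walking")
  pi <- predict_with_interval(m, 0.28)
  expect_equal(pi$lwr, pi$fit, tolerance = 1e-8)
  expect_equal(pi$upr, pi$fit, tolerance = 1e-8)
})

test_that("Shapiro-Wilk residual check behaves under the null, violation and degeneracy", {
  specs <- default_gait_specs()[1, ]
  p_null <- vapply(1:200, function(i) {
    trk <- generate_trackways(specs, seed = 1000 + i)
    residual_normality(fit_gait_model(trk, "walking"))$p_value
  }, 0)
  expect_gte(mean(p_null > 0.05), 0.90)

  # gross violation: Cauchy-tailed residuals
  set.seed(99)
  p_heavy <- vapply(1:100, function(i) {
    l <- runif(48, 0.225, 0.322)
    u <- 3.2 * l - 0.23 + 0.05 * rt(48, df = 1)
    trk <- tibble::tibble(id = as.character(1:48), l_stride = l, n_strides = 1L,
                          gait = "walking", u_measured = pmax(u, 0.01))
    residual_normality(fit_gait_model(trk, "walking"))$p_value
  }, 0)
  expect_gt(mean(p_heavy < 0.05), 0.5)

  exact <- fit_gait_model(
    exact_trackways(seq(0.23, 0.32, length.out = 8), 3.2, -0.23, "walking"),
    "walking")
  expect_warning(res <- residual_normality(exact), "zero variance")
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
})

test_that("models reloaded from the plain-text file predict identically", {
  trk <- generate_trackways(seed = 8)
  models <- fit_gait_models(trk)
  tf <- tempfile(fileext = ".yml")
  write_gait_models(models, tf)
  back <- read_gait_models(tf)
  expect_equal(glance(back), glance(models), tolerance = 1e-12)
  l_new <- c(0.25, 0.35, 0.5)
  for (g in names(models)) {
    expect_equal(predict_with_interval(back[[g]], l_new),
                 predict_with_interval(models[[g]], l_new), tolerance = 1e-12)
  }
  expect_error(residual_normality(back$walking), "refit")
})

test_that("tidy and glance expose the model terms and summary row", {
  trk <- generate_trackways(seed = 2)
  models <- fit_gait_models(trk)
  td <- tidy(models)
  expect_equal(nrow(td), 6L)  # 3 gaits x 2 terms
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(models)
  expect_equal(gl$gait, c("walking", "grounded_running", "aerial_running"))
  expect_true(all(gl$r.squared >= 0 & gl$r.squared <= 1))
  expect_equal(gl$df2, gl$n - 2L)
})
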