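# Independent oracles and small fixture builders used across the suite.

# Normal-equation OLS, independent of stats::lm.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Exact (noiseless) trackway table on a given line, for one gait.
exact_trackways <- function(l, slope, intercept, gait = "walking",
                            prefix = gait) {
  tibble::tibble(
    id = sprintf("%s_%02d", prefix, seq_along(l)),
    l_stride = l,
    n_strides = 3L,
    gait = gait,
    u_measured = slope * l + intercept
  )
}

# Fit a gait_model whose observed stride range is exactly [l_min, l_max].
range_model <- function(gait, l_min, l_max, slope = 3, intercept = 0, n = 5) {
  l <- seq(l_min, l_max, length.out = n)
  fit_gait_model(exact_trackways(l, slope, intercept, gait), gait)
}

ptarmigan <- species_profile()
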