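test_that("tracer incubation validates its invariants", {
  expect_error(tracer_incubation(time_h = c(0, 24, 24),
                                 no2_15n = c(0, 1, 2),
                                 no3_15n = c(0, 0, 0)),
               "strictly increasing")
  expect_error(tracer_incubation(time_h = c(0, 24), no2_15n = c(0, -1),
                                 no3_15n = c(0, 0)),
               "non-negative")
  inc <- tracer_incubation(time_h = c(0, 24, 48), no2_15n = c(0, 1, 2),
                           no3_15n = c(1, 1, 1))
  expect_equal(inc$time_d, c(0, 1, 2))
  expect_equal(inc$nox_15n, c(1, 2, 3))
})

test_that("labeling fraction matches its definition and the field regime", {
  expect_gt(labeling_fraction(10, 0.07), 0.99)
  expect_equal(round(labeling_fraction(10, 0.07), 4), 0.993)
  expect_equal(labeling_fraction(10, 10), 0.5)
  expect_equal(labeling_fraction(10, 0), 1)
  expect_error(labeling_fraction(0, 1), "> 0")
})

test_that("exact linear series recovers the slope with R2 = 1", {
  fit <- potential_rate(make_linear_incubation(6, times_h = c(0, 24, 48)))
  expect_equal(fit$slope, 6)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$significant)
  expect_equal(fit$p_value, .Machine$double.xmin)
})

test_that("flat series is non-significant with zero slope", {
  inc <- tracer_incubation(time_h = c(0, 24, 48), no2_15n = c(5, 5, 5),
                           no3_15n = c(0, 0, 0))
  fit <- potential_rate(inc)
  expect_equal(fit$slope, 0)
  expect_false(fit$significant)
  expect_equal(fit$p_value, 1)
})

test_that("rate estimation errors on insufficient or degenerate input", {
  expect_error(potential_rate(
    tracer_incubation(time_h = c(0, 24), no2_15n = c(0, 1),
                      no3_15n = c(0, 0))),
    "at least 3")
})

test_that("OLS slope equals the closed-form oracle on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    t_h <- sort(c(0, cumsum(runif(n - 1, 1, 24))))
    y <- abs(rnorm(n, 2, 3))
    inc <- tracer_incubation(time_h = t_h, no2_15n = y, no3_15n = rep(0, n))
    fit <- potential_rate(inc)
    expect_equal(fit$slope, ols_slope_oracle(t_h / 24, y))
  }
})

test_that("slope is invariant under adding a constant to all 15NOx values", {
  set.seed(9)
  t_h <- c(0, 12, 24, 48)
  y <- 6 * t_h / 24 + rnorm(4, 0, 0.3)
  y <- y - min(y) # keep concentrations non-negative
  f1 <- potential_rate(tracer_incubation(time_h = t_h, no2_15n = y,
                                         no3_15n = rep(0, 4)))
  f2 <- potential_rate(tracer_incubation(time_h = t_h, no2_15n = y + 5,
                                         no3_15n = rep(0, 4)))
  expect_equal(f1$slope, f2$slope)
})

test_that("one-tailed p agrees with the t-distribution on a noisy fit", {
  set.seed(3)
  t_h <- c(0, 12, 24, 48)
  y <- pmax(6 * t_h / 24 + rnorm(4, 0, 0.5), 0)
  inc <- tracer_incubation(time_h = t_h, no2_15n = y, no3_15n = rep(0, 4))
  fit <- potential_rate(inc)
  lmfit <- lm(y ~ I(t_h / 24))
  tval <- summary(lmfit)$coefficients[2, "t value"]
  expect_equal(fit$p_value, pt(tval, df = 2, lower.tail = FALSE))
})

test_that("labeling correction divides the slope by the labeling fraction", {
  inc <- make_linear_incubation(6)
  plain <- potential_rate(inc)
  corr <- potential_rate(inc, correct_labeling = TRUE)
  expect_equal(corr$slope, plain$slope / labeling_fraction(10, 0.07))
  expect_gt(corr$slope, plain$slope) # correction can only raise the rate
})

test_that("model-object methods behave like a fitted regression", {
  inc <- make_linear_incubation(6, times_h = c(0, 12, 24, 48))
  fit <- potential_rate(inc)
  expect_equal(unname(coef(fit)["slope"]), 6)
  expect_equal(predict(fit, 1), c("1" = 6))
  expect_equal(unname(residuals(fit)), rep(0, 4))
  expect_equal(fitted(fit), predict(fit))
  expect_output(print(fit), "rate: 6 nmol")
  expect_output(print(summary(fit)), "linear model")
})

test_that("replicate pooling averages significant slopes with their spread", {
  incs <- lapply(c(5, 6, 7), make_linear_incubation)
  pooled <- replicate_rate(incs)
  expect_equal(uv_value(pooled), 6)
  expect_equal(uv_sd(pooled), 1)
  expect_equal(attr(pooled, "n_used"), 3L)
  # three identical noiseless replicates: zero spread
  same <- replicate_rate(lapply(rep(5.67, 3), make_linear_incubation))
  expect_equal(uv_value(same), 5.67)
  expect_equal(uv_sd(same), 0)
})

test_that("all-non-significant replicates report below detection", {
  flat <- tracer_incubation(time_h = c(0, 24, 48), no2_15n = c(5, 5, 5),
                            no3_15n = c(0, 0, 0))
  pooled <- replicate_rate(list(flat, flat))
  expect_true(attr(pooled, "below_detection"))
  expect_true(is.na(uv_value(pooled)))
})

test_that("slope estimator is unbiased and well-covered under noise", {
  cfg <- scenario_config(seed = 1, tracer_slope_nmol_l_d = 6,
                         tracer_sigma_nmol_l = 0.3, n_tracer_rep = 1L)
  n_sim <- 1000
  slopes <- numeric(n_sim)
  covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    inc <- gen_tracer_incubation(
      scenario_config(seed = i, tracer_slope_nmol_l_d = 6,
                      tracer_sigma_nmol_l = 0.3, n_tracer_rep = 1L))[[1]]
    fit <- potential_rate(inc)
    slopes[i] <- fit$slope
    ci <- confint(fit)
    covered[i] <- ci[1] <= 6 && 6 <= ci[2]
  }
  expect_lt(abs(mean(slopes) - 6) / 6, 0.01) # bias < 1%
  expect_equal(mean(covered), 0.95, tolerance = 0.025) # 95% CI coverage
})

test_that("replicate triplicates recover the true rate within 2 SEM", {
  true_slope <- 6.06
  cfg <- scenario_config(seed = 20, tracer_slope_nmol_l_d = true_slope,
                         tracer_sigma_nmol_l = 0.37)
  pooled <- replicate_rate(gen_tracer_incubation(cfg))
  sem <- uv_sd(pooled) / sqrt(attr(pooled, "n_used"))
  expect_lt(abs(uv_value(pooled) - true_slope), 2 * sem + 1e-9)
})
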