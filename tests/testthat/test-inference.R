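test_that("the Wald quadratic form has its defining properties", {
  set.seed(21)
  p <- 6
  A <- matrix(rnorm(p * p), p)
  V <- crossprod(A) + diag(p) * 0.1
  beta <- rnorm(p)
  ## zero coefficients give a zero statistic
  w0 <- phenogamm:::wald_chisq(rep(0, p), V, p)
  expect_equal(w0$statistic, 0)
  expect_equal(stats::pchisq(w0$statistic, w0$rank, lower.tail = FALSE), 1)
  ## invariance under orthogonal rotation of the basis
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  w1 <- phenogamm:::wald_chisq(beta, V, p)
  w2 <- phenogamm:::wald_chisq(drop(Q %*% beta), Q %*% V %*% t(Q), p)
  expect_equal(w1$statistic, w2$statistic, tolerance = 1e-8)
})

test_that("smooth tests detect strong signals and report a valid rank", {
  set.seed(23)
  pan <- quick_panel(function(t, cal) 1.2 * cos(2 * pi * (cal - 1) / 12),
                     n_plants = 10, n_months = 96)
  fit <- pgamm(status ~ s(month_index, k = 8) +
                 s(calendar_month, k = 8, bs = "cc"), data = pan)
  ts2 <- smooth_test(fit, "s(calendar_month)")
  expect_lt(ts2$p_value, 1e-6)
  expect_gte(ts2$rank_r, 1L)
  expect_lte(ts2$rank_r, 6L)
  expect_gte(ts2$statistic, 0)
  ## term matching by covariate name works too
  expect_equal(smooth_test(fit, "calendar_month")$statistic, ts2$statistic)
  expect_error(smooth_test(fit, "no_such_term"), "not found")
})

test_that("credible bands are ordered, nested across levels, and collapse with zero covariance", {
  set.seed(25)
  pan <- quick_panel(function(t, cal) 0.8 * sin(2 * pi * cal / 12),
                     n_plants = 8, n_months = 72)
  fit <- pgamm(status ~ s(calendar_month, k = 7, bs = "cc"), data = pan)
  at <- seq(0.5, 11.5, by = 0.5)
  b95 <- credible_band(fit, "s(calendar_month)", at, level = 0.95)
  b80 <- credible_band(fit, "s(calendar_month)", at, level = 0.80)
  expect_true(all(b95$lower <= b95$fit & b95$fit <= b95$upper))
  expect_true(all(b95$upper - b95$lower > b80$upper - b80$lower))
  expect_equal(b95$fit, b80$fit)
  ## zero posterior covariance collapses the band onto the fitted curve
  fit0 <- fit
  fit0$Vp <- matrix(0, nrow(fit$Vp), ncol(fit$Vp))
  b0 <- credible_band(fit0, "s(calendar_month)", at)
  expect_equal(b0$lower, b0$fit)
  expect_equal(b0$upper, b0$fit)
  expect_error(credible_band(fit, "s(calendar_month)", at, level = 1.2),
               "level")
})

test_that("the likelihood ratio test is zero for identical models", {
  set.seed(27)
  pan <- quick_panel(function(t, cal) rep(0.2, length(t)), n_plants = 5,
                     n_months = 48)
  f1 <- pgamm(status ~ s(month_index, k = 6), data = pan)
  f2 <- pgamm(status ~ s(month_index, k = 6), data = pan)
  cmp <- lrt(f1, f2)
  expect_equal(cmp$statistic, 0, tolerance = 1e-6)
  expect_equal(cmp$df, 0L)
  expect_equal(cmp$p_value, 1)
})

test_that("the structural df rule gives the published degrees of freedom", {
  set.seed(29)
  profiles <- list(species_profile("spA", 6, trend_type = "nonlinear",
                                   trend_params = list(amplitude = 1.5),
                                   seasonal_amplitude = 1.2, re_sd = 0.4,
                                   lag_coef = 0.6))
  pan <- generate_panel(profiles, n_months = 60, missing_rate = 0, seed = 4)
  fits <- lapply(c("M1", "M2", "M3", "M4", "M5"), fit_model, panel = pan,
                 with_mixed = TRUE, k_trend = 8, k_season = 6)
  names(fits) <- c("M1", "M2", "M3", "M4", "M5")
  expect_equal(lrt(fits$M1, fits$M5)$df, 3L)
  expect_equal(lrt(fits$M1, fits$M2)$df, 1L)
  expect_equal(lrt(fits$M1, fits$M3)$df, 1L)
  expect_equal(lrt(fits$M1, fits$M4)$df, 2L)
  ## the rule is purely structural: identical without the mixed terms
  fits0 <- lapply(c("M1", "M2", "M5"), fit_model, panel = pan,
                  with_mixed = FALSE, k_trend = 8, k_season = 6)
  expect_equal(lrt(fits0[[1]], fits0[[3]])$df, 3L)
  expect_equal(lrt(fits0[[1]], fits0[[2]])$df, 1L)
})
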