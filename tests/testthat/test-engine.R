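test_that("the unpenalized engine matches an independent Newton logistic regression", {
  set.seed(7)
  pan <- quick_panel(function(t, cal) 0.4 * sin(t / 6) - 0.2, n_plants = 5,
                     n_months = 80)
  design <- build_design(
    status ~ s(month_index, k = 6) + s(calendar_month, k = 5, bs = "cc"),
    pan)
  fit <- fit_penalized(design,
                       lambdas = list("s(month_index)" = 0,
                                      "s(calendar_month)" = 0))
  oracle <- newton_logistic(design$X, design$y)
  expect_equal(unname(coef(fit)), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(fit$deviance, oracle$deviance, tolerance = 1e-6)
  ## and equals the stats::glm deviance too
  g <- stats::glm.fit(design$X, design$y, family = stats::binomial())
  expect_equal(fit$deviance, g$deviance, tolerance = 1e-6)
})

test_that("intercept-only fit returns the logit of the response mean", {
  d <- data.frame(y = rep(c(0, 1), 50))
  expect_equal(unname(coef(pgamm(y ~ 1, data = d))), 0, tolerance = 1e-9)
  d2 <- data.frame(y = rep(c(0, 1, 1, 1), 25))
  expect_equal(unname(coef(pgamm(y ~ 1, data = d2))),
               stats::qlogis(0.75), tolerance = 1e-8)
})

test_that("penalized fits match an IRLS oracle in the original basis parameterization", {
  set.seed(11)
  pan <- quick_panel(function(t, cal) 0.8 * cos(2 * pi * cal / 12),
                     n_plants = 6, n_months = 72)
  for (lambda in c(0.5, 20)) {
    design <- build_design(
      status ~ s(calendar_month, k = 7, bs = "cc"), pan)
    fit <- fit_penalized(design,
                         lambdas = list("s(calendar_month)" = lambda))
    bx <- build_basis(smooth_spec("calendar_month", k = 7, bs = "cc",
                                  period = 12), pan$calendar_month)
    oracle <- pirls_original_basis(bx$design, bx$penalty, pan$status, lambda)
    expect_equal(fit$fitted.values, oracle$fitted, tolerance = 1e-6)
  }
})

test_that("an enormous penalty shrinks a smooth to its unpenalized null space", {
  set.seed(3)
  pan <- quick_panel(function(t, cal) 0.9 * cos(2 * pi * cal / 12),
                     n_plants = 8, n_months = 96)
  fit <- pgamm(status ~ s(month_index, k = 8) +
                 s(calendar_month, k = 8, bs = "cc"),
               data = pan,
               sp = c("s(month_index)" = 1e8, "s(calendar_month)" = 1e8))
  ## cyclic term: centering removed its constant null space -> flat zero
  cb <- credible_band(fit, "s(calendar_month)", seq(0.5, 11.5, 1))
  expect_lt(max(abs(cb$fit)), 1e-3)
  ## trend term: only its linear component survives
  cb2 <- credible_band(fit, "s(month_index)", 1:96)
  expect_lt(max(abs(diff(cb2$fit, differences = 2))), 1e-5)
})

test_that("effective degrees of freedom shrink monotonically in lambda", {
  set.seed(5)
  pan <- quick_panel(function(t, cal) 0.7 * sin(2 * pi * cal / 12),
                     n_plants = 6, n_months = 72)
  design <- build_design(status ~ s(calendar_month, k = 8, bs = "cc"), pan)
  edfs <- vapply(c(1e-4, 1e-2, 1, 1e2, 1e4), function(l) {
    f <- fit_penalized(design, lambdas = list("s(calendar_month)" = l))
    f$edf_smooth[["s(calendar_month)"]]
  }, 0)
  expect_true(all(diff(edfs) < 0))
  expect_true(all(edfs > 0 & edfs <= 6))
})

test_that("the posterior covariance is symmetric positive semi-definite", {
  set.seed(9)
  pan <- quick_panel(function(t, cal) 0.5 * sin(t / 10), n_plants = 5,
                     n_months = 60)
  fit <- pgamm(status ~ s(month_index, k = 7), data = pan)
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("complete separation triggers the ridge fallback with a warning", {
  d <- data.frame(y = rep(c(0, 1), each = 20), x = c(1:20, 41:60))
  expect_warning(fit <- pgamm(y ~ x, data = d), "separation|ridge")
  expect_true(all(is.finite(coef(fit))))
  expect_true(fit$ridge)
})

test_that("maximum-likelihood selection shrinks absent signals and keeps real ones", {
  set.seed(13)
  ## pure noise: the seasonal smooth should be heavily shrunk
  pan0 <- quick_panel(function(t, cal) rep(0, length(t)), n_plants = 10,
                      n_months = 96)
  f0 <- pgamm(status ~ s(calendar_month, k = 8, bs = "cc"), data = pan0)
  expect_lt(f0$edf_smooth[["s(calendar_month)"]], 1.5)
  ## strong annual signal: clearly more than one effective df
  pan1 <- quick_panel(function(t, cal) 1.2 * cos(2 * pi * (cal - 2) / 12),
                      n_plants = 10, n_months = 96)
  f1 <- pgamm(status ~ s(calendar_month, k = 8, bs = "cc"), data = pan1)
  expect_gt(f1$edf_smooth[["s(calendar_month)"]], 2)
  expect_true(f1$converged)
})

test_that("prediction reproduces the training linear predictor and respects new data", {
  set.seed(15)
  pan <- quick_panel(function(t, cal) 0.6 * cos(2 * pi * cal / 12),
                     n_plants = 5, n_months = 60)
  fit <- pgamm(status ~ s(calendar_month, k = 6, bs = "cc"), data = pan)
  expect_equal(predict(fit), fit$linear.predictors, tolerance = 1e-10)
  pr <- predict(fit, newdata = pan[1:12, ], type = "response",
                se.fit = TRUE)
  expect_equal(pr$fit, fit$fitted.values[1:12], tolerance = 1e-10)
  expect_true(all(pr$se.fit >= 0))
})
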