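test_that("scaled forward-backward equals brute-force path enumeration", {
  model <- list(initial = c(0.6, 0.4),
                transition = matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
                emission = c(0.2, 0.9))
  for (series in list(c(1, 1, NA, 0, 1), c(0, NA, NA, 1, 1),
                      c(1, 0, 1, 0, 1))) {
    fb <- phenogamm:::hmm_forward_backward(series, model)
    oracle <- hmm_enumerate(series, model)
    expect_lt(max(abs(fb$gamma - oracle$gamma)), 1e-10)
    expect_lt(abs(fb$log_lik - oracle$log_lik), 1e-10)
  }
})

test_that("a missing month flanked by fruiting runs under a persistent model is imputed 1", {
  model <- list(initial = c(0.5, 0.5),
                transition = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                emission = c(0.1, 0.9))
  series <- c(1, 1, NA, 1, 1)
  oracle <- hmm_enumerate(series, model)
  post_oracle <- drop(oracle$gamma[3, ] %*% model$emission)
  comp <- smooth_impute(series, model)
  expect_equal(attr(comp, "posterior")[3], post_oracle, tolerance = 1e-10)
  expect_gt(post_oracle, 0.5)
  expect_equal(as.numeric(comp), c(1, 1, 1, 1, 1))
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(41)
  for (r in 1:4) {
    ser <- rbinom(60, 1, runif(1, 0.2, 0.8))
    ser[sample(60, 6)] <- NA
    m <- fit_hmm(ser)
    expect_true(all(diff(m$log_lik_trace) > -1e-8))
    expect_true(all(abs(rowSums(m$transition) - 1) < 1e-8))
  }
})

test_that("independent fair-coin data yield near-symmetric transitions", {
  set.seed(43)
  ser <- rbinom(300, 1, 0.5)
  m <- fit_hmm(ser)
  ## stationary P(1) implied by the model should be near one half
  fb <- phenogamm:::hmm_forward_backward(ser, m)
  expect_equal(mean(drop(fb$gamma %*% m$emission)), 0.5, tolerance = 0.1)
})

test_that("imputation never alters observed months and completes the series", {
  set.seed(45)
  ser <- rbinom(95, 1, 0.4)
  ser[sample(95, 8)] <- NA
  comp <- smooth_impute(ser)
  expect_false(anyNA(comp))
  obs <- !is.na(ser)
  expect_equal(as.numeric(comp[obs]), ser[obs])
  ## no missing entries: identity
  full <- rbinom(40, 1, 0.5)
  expect_equal(as.numeric(smooth_impute(full)), full)
})

test_that("degenerate constant series are imputed constant and flagged", {
  ser <- c(1, 1, NA, 1, 1, NA, 1)
  m <- fit_hmm(ser)
  expect_true(m$degenerate)
  expect_equal(as.numeric(smooth_impute(ser, m)), rep(1, 7))
  ser0 <- c(0, 0, NA, 0)
  expect_equal(as.numeric(smooth_impute(ser0, fit_hmm(ser0))), rep(0, 4))
})

test_that("invalid HMM inputs are rejected", {
  expect_error(fit_hmm(c(NA, NA, NA, NA)), "all-missing")
  expect_error(fit_hmm(c(1, 0, 1)), "too short")
  expect_error(fit_hmm(c(1, 2, 0, 1)), "0, 1 or NA")
  bad <- list(initial = c(0.7, 0.7),
              transition = matrix(0.5, 2, 2), emission = c(0.2, 0.8))
  expect_error(phenogamm:::hmm_check(bad), "invalid HMM")
})

test_that("panel imputation fills every plant and reports the mask", {
  set.seed(47)
  profiles <- list(species_profile("spA", 4, seasonal_amplitude = 1,
                                   lag_coef = 0.8))
  pan <- generate_panel(profiles, n_months = 50, missing_rate = 0.1,
                        seed = 2)
  n_missing <- sum(is.na(pan$status))
  comp <- impute_panel(pan)
  expect_false(anyNA(comp$status))
  mask <- attr(comp, "imputation_mask")
  expect_equal(nrow(mask), n_missing)
  expect_true(all(mask$imputed_value %in% c(0, 1)))
  ## observed entries untouched
  obs <- !is.na(pan$status)
  expect_equal(comp$status[obs], pan$status[obs])
})
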