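test_that("the lag column is built within plants and never leaks across them", {
  p <- data.frame(plant_id = rep(c("a", "b"), each = 4), species = "s",
                  month_index = rep(1:4, 2), calendar_month = rep(1:4, 2),
                  status = c(1, 1, 0, 0, 0, 1, 1, 0))
  pl <- add_lag(p)
  expect_equal(pl$lag_status[pl$plant_id == "a"], c(1, 1, 0))
  expect_equal(pl$lag_status[pl$plant_id == "b"], c(0, 1, 1))
  expect_equal(attr(pl, "dropped_first_obs"), 2L)
  expect_equal(nrow(pl), 6L)
  ## duplicated (plant, month) rows are rejected
  expect_error(add_lag(rbind(p, p[1, ])), "duplicated")
  ## incomplete panels are rejected
  p2 <- p; p2$status[3] <- NA
  expect_error(add_lag(p2), "missing")
})

test_that("random intercepts require at least two plants", {
  d <- data.frame(y = rbinom(30, 1, 0.5), g = "only_one")
  expect_error(build_design(y ~ 1, d, random = ~ g), "at least two")
})

test_that("relabeling plants permutes the predicted random intercepts", {
  set.seed(31)
  b <- rnorm(8, 0, 1)
  d <- data.frame(plant_id = rep(sprintf("p%d", 1:8), each = 60))
  d$y <- rbinom(nrow(d), 1, stats::plogis(b[as.integer(factor(d$plant_id))]))
  f1 <- pgamm(y ~ 1, data = d, random = ~ plant_id)
  d2 <- d
  d2$plant_id <- chartr("12345678", "87654321", d$plant_id)
  f2 <- pgamm(y ~ 1, data = d2, random = ~ plant_id)
  r1 <- random_effects(f1)
  r2 <- random_effects(f2)
  expect_equal(unname(r1[sprintf("p%d", 1:8)]),
               unname(r2[sprintf("p%d", 8:1)]), tolerance = 1e-6)
  ## predicted intercepts approximately sum to zero
  expect_lt(abs(sum(r1)) / stats::sd(r1), 0.5)
})

test_that("a frozen random-intercept variance reproduces the plain fit", {
  set.seed(33)
  pan <- quick_panel(function(t, cal) 0.5 * cos(2 * pi * cal / 12),
                     n_plants = 6, n_months = 48)
  plain <- pgamm(status ~ s(calendar_month, k = 6, bs = "cc"), data = pan,
                 sp = c("s(calendar_month)" = 2))
  mixed <- pgamm(status ~ s(calendar_month, k = 6, bs = "cc"), data = pan,
                 random = ~ plant_id,
                 sp = c("s(calendar_month)" = 2, "re(plant_id)" = 1e10))
  expect_equal(unname(mixed$fitted.values), unname(plain$fitted.values),
               tolerance = 1e-4)
  expect_equal(unname(coef(mixed)[seq_along(coef(plain))]),
               unname(coef(plain)), tolerance = 1e-4)
})

test_that("the random-intercept standard deviation is recovered", {
  set.seed(35)
  ests0 <- ests1 <- numeric(5)
  for (r in 1:5) {
    ## sigma = 1, long series
    b <- rnorm(20, 0, 1)
    d <- data.frame(plant_id = rep(sprintf("p%02d", 1:20), each = 240))
    d$y <- rbinom(nrow(d), 1,
                  stats::plogis(b[as.integer(factor(d$plant_id))]))
    ests1[r] <- pgamm(y ~ 1, data = d, random = ~ plant_id)$re_sd
    ## sigma = 0: identical probabilities across plants
    d$y <- rbinom(nrow(d), 1, 0.5)
    ests0[r] <- pgamm(y ~ 1, data = d, random = ~ plant_id)$re_sd
  }
  expect_gt(mean(ests1), 0.7)
  expect_lt(mean(ests1), 1.3)
  expect_true(mean(ests0 < 0.1) >= 0.8)
})

test_that("joint sigma estimation matches the lme4 Laplace-ML reference", {
  library(lme4)
  for (r in 1:3) {
    set.seed(20000 + r)
    b <- rnorm(20, 0, 1)
    d <- data.frame(plant_id = rep(sprintf("p%02d", 1:20), each = 240))
    d$y <- rbinom(nrow(d), 1,
                  stats::plogis(b[as.integer(factor(d$plant_id))]))
    mine <- pgamm(y ~ 1, data = d, random = ~ plant_id)$re_sd
    g <- lme4::glmer(y ~ 1 + (1 | plant_id), data = d, family = binomial)
    expect_equal(mine, sqrt(unlist(lme4::VarCorr(g))[[1]]),
                 tolerance = 1e-3)
  }
})

test_that("the lag coefficient reflects serial dependence", {
  set.seed(37)
  mk_panel <- function(p_stay) {
    n_pl <- 15; n_mo <- 80
    rows <- lapply(seq_len(n_pl), function(k) {
      y <- numeric(n_mo); y[1] <- rbinom(1, 1, 0.5)
      for (t in 2:n_mo)
        y[t] <- rbinom(1, 1, if (y[t - 1] == 1) p_stay else 1 - p_stay)
      data.frame(plant_id = sprintf("p%02d", k), species = "s",
                 month_index = 1:n_mo,
                 calendar_month = (0:(n_mo - 1)) %% 12 + 1, status = y)
    })
    do.call(rbind, rows)
  }
  ## strongly persistent chain: positive lag coefficient
  f_dep <- fit_model("M5", mk_panel(0.85), with_mixed = TRUE)
  est <- coef(f_dep)["lag_status"]
  se <- sqrt(vcov(f_dep)[names(est), names(est)])
  expect_gt(unname(est - 2 * se), 0)
  ## independent data: lag coefficient within 2 SE of zero in most runs
  hits <- 0L
  for (r in 1:5) {
    f_ind <- fit_model("M5", mk_panel(0.5), with_mixed = TRUE)
    est <- coef(f_ind)["lag_status"]
    se <- sqrt(vcov(f_ind)[names(est), names(est)])
    if (abs(est) < 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
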