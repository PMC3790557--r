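test_that("centered bases have the advertised dimensions and identifiability", {
  bx <- build_basis(smooth_spec("t", k = 10), 1:120)
  expect_equal(dim(bx$design), c(120L, 9L))
  expect_lt(max(abs(colSums(bx$design))), 1e-10)
  expect_equal(bx$null_space_dim, 1L)          # the centered linear function
  expect_equal(bx$penalty, t(bx$penalty))
  expect_gte(min(eigen(bx$penalty, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)

  bc <- build_basis(smooth_spec("m", k = 8, bs = "cc", period = 12),
                    rep(1:12, 10))
  expect_equal(dim(bc$design), c(120L, 6L))    # -1 periodicity, -1 centering
  expect_equal(bc$null_space_dim, 0L)
  expect_lt(max(abs(colSums(bc$design))), 1e-10)
})

test_that("constants and linear functions are unpenalized in the raw cubic basis", {
  kn <- c(0, 1, 2.5, 4, 7, 10)
  mats <- phenogamm:::cr_matrices(kn)
  cons <- rep(1, 6)
  expect_lt(abs(drop(t(cons) %*% mats$S %*% cons)), 1e-10)
  expect_lt(abs(drop(t(kn) %*% mats$S %*% kn)), 1e-10)
  ## cyclic penalty annihilates constants only
  knc <- seq(0, 12, length.out = 8)
  mc <- phenogamm:::cc_matrices(knc)
  expect_lt(abs(drop(t(rep(1, 7)) %*% mc$S %*% rep(1, 7))), 1e-10)
})

test_that("basis-represented functions interpolate like natural/periodic cubic splines", {
  kn <- c(0, 1, 2.5, 4, 7, 10)
  beta <- c(0.3, -1, 2, 0.5, 1.2, -0.4)
  xs <- seq(0, 10, by = 0.05)
  mine <- drop(phenogamm:::cr_eval(xs, kn) %*% beta)
  oracle <- stats::spline(kn, beta, xout = xs, method = "natural")$y
  expect_lt(max(abs(mine - oracle)), 1e-10)

  knc <- seq(0, 12, length.out = 8)
  bc <- c(0.5, -0.3, 1, 2, -1, 0.2, 0.7)
  xc <- seq(0, 12, by = 0.05)
  mine <- drop(phenogamm:::cc_eval(xc, knc) %*% bc)
  oracle <- stats::spline(knc, c(bc, bc[1]), xout = xc, method = "periodic")$y
  expect_lt(max(abs(mine - oracle)), 1e-10)
})

test_that("penalty quadratic form matches the numerically integrated squared second derivative", {
  set.seed(42)
  kn <- seq(0, 10, length.out = 7)
  mats <- phenogamm:::cr_matrices(kn)
  fine <- seq(0, 10, length.out = 20001)
  h <- fine[2] - fine[1]
  for (r in 1:3) {
    beta <- rnorm(7)
    f <- drop(phenogamm:::cr_eval(fine, kn, mats) %*% beta)
    num <- sum((diff(f, differences = 2) / h^2)^2) * h
    expect_equal(drop(t(beta) %*% mats$S %*% beta), num, tolerance = 0.01)
  }
  knc <- seq(0, 12, length.out = 8)
  mc <- phenogamm:::cc_matrices(knc)
  finec <- seq(0, 12, length.out = 24001)
  hc <- finec[2] - finec[1]
  for (r in 1:3) {
    beta <- rnorm(7)
    f <- drop(phenogamm:::cc_eval(finec, knc, mc) %*% beta)
    num <- sum((diff(f, differences = 2) / hc^2)^2) * hc
    expect_equal(drop(t(beta) %*% mc$S %*% beta), num, tolerance = 0.01)
  }
})

test_that("cyclic evaluation is exactly periodic", {
  spec <- smooth_spec("m", k = 8, bs = "cc", period = 12)
  bx <- build_basis(spec, rep(1:12, 10))
  beta <- seq(-0.5, 0.5, length.out = 6)
  ## dyadic evaluation points reduce modulo the period without rounding
  v <- seq(0.25, 11.75, by = 0.25)
  expect_identical(evaluate_smooth(bx, beta, v),
                   evaluate_smooth(bx, beta, v + 12))
  ## non-dyadic points agree to numerical tolerance
  w <- seq(0.1, 11.9, by = 0.4)
  expect_equal(evaluate_smooth(bx, beta, w),
               evaluate_smooth(bx, beta, w + 12), tolerance = 1e-12)
  expect_equal(evaluate_smooth(bx, beta, 0.5),
               evaluate_smooth(bx, beta, 12.5))
})

test_that("evaluate_smooth reproduces training fit and handles edge cases", {
  bx <- build_basis(smooth_spec("t", k = 6), 1:40)
  beta <- rnorm(5)
  expect_equal(evaluate_smooth(bx, beta, 1:40),
               drop(bx$design %*% beta))
  expect_identical(evaluate_smooth(bx, rep(0, 5), c(3.3, 17)), c(0, 0))
  expect_error(evaluate_smooth(bx, rep(0, 4), 1:3), "does not match")
  expect_warning(evaluate_smooth(bx, beta, 45), "extrapolat")
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(build_basis(smooth_spec("t", k = 10), rep(1:5, 10)),
               "degenerate basis")
  expect_error(build_basis(smooth_spec("t", k = 5), c(1, 2, NA, 4, 5, 6)),
               "non-finite")
  expect_error(smooth_spec("t", k = 2), "k")
  expect_error(smooth_spec("m", k = 5, bs = "cc"), "period")
  expect_error(smooth_spec("t", k = 4, knots = c(1, 3, 2, 4)),
               "strictly increasing")
  expect_error(smooth_spec("m", k = 4, bs = "cc", period = 12,
                           knots = c(0, 3, 6, 9)),
               "one period")
})

test_that("raw bases and penalties agree with the mgcv cr/cc constructions", {
  library(mgcv)
  x <- 1:120
  kn <- seq(1, 120, length.out = 10)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = 10),
                        data = data.frame(x = x), knots = list(x = kn),
                        absorb.cons = FALSE, scale.penalty = FALSE)[[1]]
  expect_lt(max(abs(sm$X - phenogamm:::cr_eval(x, kn))), 1e-10)
  expect_lt(max(abs(sm$S[[1]] - phenogamm:::cr_matrices(kn)$S)), 1e-10)

  xc <- rep(1:12, 10)
  knc <- seq(0, 12, length.out = 8)
  smc <- mgcv::smoothCon(mgcv::s(xc, bs = "cc", k = 8),
                         data = data.frame(xc = xc), knots = list(xc = knc),
                         absorb.cons = FALSE, scale.penalty = FALSE)[[1]]
  expect_lt(max(abs(smc$X - phenogamm:::cc_eval(xc, knc))), 1e-10)
  expect_lt(max(abs(smc$S[[1]] - phenogamm:::cc_matrices(knc)$S)), 1e-10)
})
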