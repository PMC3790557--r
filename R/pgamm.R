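#' Fit a binomial additive (mixed) model for phenology panels
#'
#' The workhorse of the package: fits a logit-link binomial additive model
#' with penalized regression spline smooths (natural cubic for long-term
#' trends, cyclic cubic for calendar seasonality), optional per-plant random
#' intercepts, and any parametric terms (e.g. a linear month index, or the
#' lag-1 fruit state from [add_lag()]). Smoothing parameters and the
#' random-intercept standard deviation are estimated jointly by maximizing a
#' Laplace-approximate marginal likelihood; alternatively all smoothing
#' parameters can be fixed via `sp`.
#'
#' The penalty on each smooth is the integrated squared second derivative;
#' viewing it as a Gaussian prior yields the Bayesian posterior coefficient
#' covariance used by [credible_band()] and [smooth_test()].
#'
#' @param formula Model formula, e.g.
#'   `status ~ s(month_index, k = 10) + s(calendar_month, k = 8, bs = "cc")`.
#' @param data Data frame with the response (0/1, no missing values) and
#'   covariates.
#' @param random Optional one-sided formula for random intercepts,
#'   e.g. `~ plant_id`.
#' @param sp Optional named vector of fixed smoothing parameters (one per
#'   smooth term, plus the random-intercept block `re(<var>)` as
#'   `1/sigma^2`). When supplied, no outer optimization is performed.
#' @param ... Passed to [select_lambda_ml()] (e.g. `rho0`, `reltol`).
#' @return An object of class `"pgamm"`: a list with `coefficients`, `Vp`
#'   (posterior covariance), `sp`, `re_sd`, `edf_smooth`, `deviance`,
#'   `log_lik` (Laplace marginal log-likelihood), `fitted.values`,
#'   `converged`, and the `design`. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `vcov`, `fitted`, `residuals`, `predict`, `plot`, `simulate`,
#'   `anova`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(t = rep(1:60, each = 4))
#' d$m <- (d$t - 1) %% 12 + 1
#' d$y <- rbinom(nrow(d), 1, plogis(0.8 * sin(2 * pi * d$m / 12)))
#' fit <- pgamm(y ~ s(t, k = 8) + s(m, k = 6, bs = "cc"), data = d)
#' summary(fit)
pgamm <- function(formula, data, random = NULL, sp = NULL, ...) {
  design <- build_design(formula, data, random = random)
  fit <- if (!is.null(sp)) {
    fit_penalized(design, lambdas = sp)
  } else {
    select_lambda_ml(design, ...)
  }
  fit$call <- match.call()
  fit
}

#' @export
print.pgamm <- function(x, ...) {
  cat("Binomial additive model (logit link)\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("n = %d, deviance = %.2f, marginal logLik = %.2f%s\n",
              x$n_obs, x$deviance, x$log_lik,
              if (!x$converged) "  [NOT converged]" else ""))
  if (length(x$edf_smooth)) {
    cat("Smooth terms (edf):\n")
    for (nm in names(x$edf_smooth))
      cat(sprintf("  %-22s edf = %5.2f  lambda = %.4g\n",
                  nm, x$edf_smooth[[nm]], x$sp[[nm]]))
  }
  if (!is.null(x$design$re))
    cat(sprintf("Random intercepts %s: sd = %.3f\n",
                x$design$re$label, x$re_sd))
  invisible(x)
}

#' @export
coef.pgamm <- function(object, ...) object$coefficients

#' @export
logLik.pgamm <- function(object, ...) {
  structure(object$log_lik, df = sum(object$edf), class = "logLik")
}

#' @export
vcov.pgamm <- function(object, ...) object$Vp

#' @export
fitted.pgamm <- function(object, ...) object$fitted.values

#' @export
residuals.pgamm <- function(object,
                            type = c("deviance", "pearson", "working"), ...) {
  type <- match.arg(type)
  y <- object$design$y
  mu <- object$fitted.values
  switch(type,
         deviance = sign(y - mu) *
           sqrt(pmax(0, -2 * (y * log(pmax(mu, 1e-12)) +
                              (1 - y) * log(pmax(1 - mu, 1e-12))))),
         pearson = (y - mu) / sqrt(pmax(mu * (1 - mu), 1e-12)),
         working = (y - mu) / pmax(mu * (1 - mu), 1e-10))
}

## rows of the full model matrix for new data (random effects: zero unless
## the level was seen in fitting)
predict_matrix <- function(design, newdata) {
  n <- nrow(newdata)
  par_labels <- setdiff(design$par_labels, "(Intercept)")
  ## rebuild the parametric block from the stored formula's parametric terms
  tf <- stats::terms(design$formula, specials = "s", data = newdata)
  labels <- attr(tf, "term.labels")
  par_terms <- labels[!grepl("^s\\(", labels)]
  Xpar <- if (length(par_terms)) {
    stats::model.matrix(stats::reformulate(par_terms, intercept = TRUE),
                        newdata)
  } else matrix(1, n, 1)
  X <- matrix(0, n, design$p)
  X[, design$par_cols] <- Xpar
  for (sm in design$smooths) {
    xv <- newdata[[sm$spec$covariate]]
    if (is.null(xv)) stop("covariate '", sm$spec$covariate,
                          "' missing from newdata")
    Xc <- basis_rows(sm$expansion, xv)
    X[, sm$cols] <- Xc %*% sm$Tmap     # back to the reparameterized columns
  }
  if (!is.null(design$re)) {
    g <- as.character(newdata[[design$re$var]])
    idx <- match(g, design$re$levels)
    seen <- !is.na(idx)
    X[cbind(which(seen), design$re$cols[idx[seen]])] <- 1
  }
  X
}

#' @export
predict.pgamm <- function(object, newdata = NULL,
                          type = c("link", "response"), se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
    X <- object$design$X
  } else {
    X <- predict_matrix(object$design, newdata)
    eta <- drop(X %*% object$coefficients)
  }
  out <- if (type == "response") stats::plogis(eta) else eta
  if (se.fit) {
    se <- sqrt(pmax(0, rowSums((X %*% object$Vp) * X)))
    if (type == "response") {
      mu <- stats::plogis(eta)
      se <- se * mu * (1 - mu)       # delta method on the logit scale
    }
    list(fit = out, se.fit = se)
  } else out
}

#' @export
simulate.pgamm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(mu), 1L, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Predicted (shrunk) random intercepts
#'
#' @param object A `"pgamm"` fit with random intercepts.
#' @return Named vector of predicted group-level intercepts (logit scale).
#' @export
random_effects <- function(object) {
  stopifnot(inherits(object, "pgamm"))
  if (is.null(object$design$re)) stop("model has no random intercepts")
  b <- object$coefficients[object$design$re$cols]
  names(b) <- object$design$re$levels
  b
}

#' @export
summary.pgamm <- function(object, ...) {
  tests <- lapply(names(object$design$smooths),
                  function(nm) smooth_test(object, nm))
  names(tests) <- names(object$design$smooths)
  structure(list(fit = object, tests = tests), class = "summary.pgamm")
}

#' @export
print.summary.pgamm <- function(x, ...) {
  print(x$fit)
  if (length(x$tests)) {
    cat("\nApproximate significance of smooth terms:\n")
    for (tt in x$tests)
      cat(sprintf("  %-22s edf = %5.2f  chi-sq = %8.2f  rank = %d  p = %.4g\n",
                  tt$term_name, tt$edf, tt$statistic, tt$rank_r, tt$p_value))
  }
  invisible(x)
}

#' @export
plot.pgamm <- function(x, level = 0.95, n_grid = 200, ...) {
  sms <- x$design$smooths
  if (!length(sms)) {
    warning("no smooth terms to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, length(sms)))
  on.exit(graphics::par(op))
  for (sm in sms) {
    rng <- sm$expansion$x_range
    at <- seq(rng[1], rng[2], length.out = n_grid)
    cb <- credible_band(x, sm$label, at, level = level)
    graphics::plot(at, cb$fit, type = "l",
                   ylim = range(cb$lower, cb$upper),
                   xlab = sm$spec$covariate, ylab = sm$label, ...)
    graphics::lines(at, cb$lower, lty = 2)
    graphics::lines(at, cb$upper, lty = 2)
    graphics::abline(h = 0, col = "grey")
  }
  invisible(x)
}
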