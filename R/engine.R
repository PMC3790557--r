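## Core penalized IRLS machinery for binomial logit additive models.
##
## The fitting objective is the penalized deviance
##   D(beta) + sum_j lambda_j * beta_j' S_j beta_j
## which, in the design's mixed-model reparameterization (identity penalties
## on the range-space blocks), has the simple diagonal penalty lambda_diag.

binom_dev <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

pirls <- function(X, y, ldiag, beta = NULL, maxit = 200L, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(beta)) {
    mu <- (y + 0.5) / 2
    eta <- stats::qlogis(mu)
    beta <- rep(0, p)
  } else {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
  }
  pdev_old <- binom_dev(y, mu) + sum(ldiag * beta^2)
  converged <- FALSE
  iter <- 0L
  ok <- TRUE
  for (it in seq_len(maxit)) {
    iter <- it
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    Xs <- X * sw
    A <- crossprod(Xs)
    diag(A) <- diag(A) + ldiag
    b <- crossprod(X, w * z)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) { ok <- FALSE; break }
    beta_new <- backsolve(ch, forwardsolve(t(ch), b))
    ## step halving on the penalized deviance
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      mu_try <- stats::plogis(eta_try)
      pdev <- binom_dev(y, mu_try) + sum(ldiag * beta_try^2)
      if (is.finite(pdev) && (pdev <= pdev_old + 1e-10 || step < 1e-4)) break
      step <- step / 2
    }
    beta <- beta_try; eta <- eta_try; mu <- mu_try
    if (abs(pdev_old - pdev) < tol * (abs(pdev) + 0.1)) {
      pdev_old <- pdev
      converged <- TRUE
      break
    }
    pdev_old <- pdev
  }
  w <- pmax(mu * (1 - mu), 1e-10)
  list(beta = drop(beta), eta = eta, mu = mu, w = w,
       deviance = binom_dev(y, mu), pdev = pdev_old,
       converged = converged && ok, iter = iter, ok = ok)
}

## Laplace-approximate marginal log-likelihood: penalized coefficients are
## integrated out as Gaussian random effects b ~ N(0, I/lambda) per block,
## unpenalized coefficients are maximized.
laplace_ml <- function(design, fit, ldiag, lambdas) {
  ll <- -fit$deviance / 2
  pen <- sum(ldiag * fit$beta^2) / 2
  logdet_S <- 0
  for (b in design$blocks) logdet_S <- logdet_S + b$rank * log(lambdas[[b$name]])
  pcols <- unlist(lapply(design$blocks, `[[`, "cols"), use.names = FALSE)
  if (length(pcols)) {
    Xp <- design$X[, pcols, drop = FALSE] * sqrt(fit$w)
    Hp <- crossprod(Xp)
    diag(Hp) <- diag(Hp) + ldiag[pcols]
    ch <- tryCatch(chol(Hp), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet_H <- 2 * sum(log(diag(ch)))
  } else logdet_H <- 0
  ll - pen + logdet_S / 2 - logdet_H / 2
}

#' Fit a penalized binomial additive model at fixed smoothing parameters
#'
#' Minimizes the penalized deviance (binomial deviance plus
#' \eqn{\sum_j \lambda_j \beta_j' S_j \beta_j}) by iteratively reweighted
#' least squares with step halving, starting from working response
#' \eqn{\mu = (y + 1/2)/2}. Deterministic given the design and lambdas.
#'
#' @param design A [build_design()] result.
#' @param lambdas Named vector/list of smoothing parameters, one per penalized
#'   block of the design (smooth terms, and the random-intercept block as
#'   `1/sigma^2` if present). May be empty when the model has no penalized
#'   terms.
#' @param beta_start Optional coefficient start (warm start).
#' @param maxit,tol IRLS iteration cap and relative penalized-deviance
#'   convergence tolerance.
#' @return A fitted model of class `"pgamm"`; see [pgamm()] for the contents.
#'   Non-convergence is flagged (`converged = FALSE`), not an error. Complete
#'   separation at zero penalty triggers a small ridge fallback with a
#'   warning (`ridge = TRUE`).
#' @export
fit_penalized <- function(design, lambdas = NULL, beta_start = NULL,
                          maxit = 200L, tol = 1e-8) {
  stopifnot(inherits(design, "pgamm_design"))
  lambdas <- as.list(lambdas %||% numeric(0))
  ldiag <- lambda_diag(design, lambdas)
  fit <- pirls(design$X, design$y, ldiag, beta = beta_start,
               maxit = maxit, tol = tol)
  ridge <- FALSE
  separated <- all(ldiag == 0) && length(ldiag) > 1L &&
    max(abs(fit$eta)) > 20 && max(abs(fit$beta)) > 50
  if (!fit$ok || any(!is.finite(fit$beta)) || separated ||
      max(abs(fit$beta)) > 1e4) {
    ## (quasi-)separation: coefficients diverge when unpenalized
    warning("apparent separation or singular fit; refitting with a small ridge")
    ridge <- TRUE
    ld2 <- ldiag + 1e-6
    ld2[1] <- ldiag[1]   # leave the intercept unpenalized
    fit <- pirls(design$X, design$y, ld2, maxit = maxit, tol = tol)
    ldiag <- ld2
  }
  finish_fit(design, fit, ldiag, lambdas, ridge = ridge)
}

finish_fit <- function(design, fit, ldiag, lambdas, ridge = FALSE,
                       optimizer = NULL) {
  sw <- sqrt(fit$w)
  Xs <- design$X * sw
  H <- crossprod(Xs)
  A <- H
  diag(A) <- diag(A) + ldiag
  ch <- chol(A)
  Vp <- chol2inv(ch)                     # Bayesian posterior covariance
  dimnames(Vp) <- list(colnames(design$X), colnames(design$X))
  edf <- rowSums(Vp * H)                 # diag of Vp %*% H
  edf_smooth <- vapply(design$smooths, function(sm) sum(edf[sm$cols]), 0)
  lam <- unlist(lambdas)
  re_sd <- if (!is.null(design$re)) {
    lr <- lambdas[[design$re$label]]
    if (is.null(lr) || lr <= 0) NA_real_ else 1 / sqrt(lr)
  } else 0
  ll_ml <- laplace_ml(design, fit, ldiag, lambdas)
  structure(list(coefficients = stats::setNames(fit$beta, colnames(design$X)),
                 Vp = Vp, edf = edf, edf_smooth = edf_smooth,
                 sp = lam, re_sd = re_sd,
                 fitted.values = fit$mu, linear.predictors = fit$eta,
                 weights = fit$w, deviance = fit$deviance,
                 log_lik = ll_ml, cond_log_lik = -fit$deviance / 2,
                 scale = 1, converged = fit$converged, iter = fit$iter,
                 ridge = ridge, n_obs = design$n,
                 design = design, ldiag = ldiag, optimizer = optimizer),
            class = "pgamm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select smoothing parameters by Laplace marginal likelihood
#'
#' Maximizes the Laplace-approximate marginal likelihood over the log
#' smoothing parameters (one per smooth term, plus the random-intercept
#' precision when present) with a derivative-free Nelder--Mead simplex
#' (golden-section search in one dimension), refitting the penalized IRLS
#' problem at each candidate. Falls back to a coarse log-lambda grid search
#' if the optimizer fails, flagging the fit.
#'
#' @param design A [build_design()] result with at least one penalized block.
#' @param rho0 Optional matrix (or vector) of starts for the log smoothing
#'   parameters, one start per row. By default two starts are used (all
#'   zeros and a moderate-shrinkage start) and the solution with the larger
#'   criterion is kept: the marginal-likelihood surface can have separate
#'   local optima (notably an over-shrunk seasonal term versus a moderately
#'   smooth one), and a single simplex can stall in either.
#' @param reltol Relative convergence tolerance of the simplex.
#' @param maxit Outer iteration cap.
#' @return A `"pgamm"` fit at the selected smoothing parameters, with an
#'   `optimizer` element recording the trace (evaluation count, convergence,
#'   whether the grid fallback fired).
#' @export
select_lambda_ml <- function(design, rho0 = NULL, reltol = 1e-4,
                             maxit = 200L) {
  stopifnot(inherits(design, "pgamm_design"))
  bnames <- names(design$blocks)
  q <- length(bnames)
  if (q == 0L) return(fit_penalized(design))
  starts <- if (is.null(rho0)) {
    rbind(rep(0, q), rep(2.5, q))
  } else {
    rbind(rho0)
  }
  starts <- pmin(pmax(starts, -15), 15)
  state <- new.env(parent = emptyenv())
  state$beta <- NULL
  state$evals <- 0L
  negml <- function(rho) {
    rho <- pmin(pmax(rho, -18), 18)
    lam <- stats::setNames(as.list(exp(rho)), bnames)
    ld <- lambda_diag(design, lam)
    ft <- pirls(design$X, design$y, ld, beta = state$beta, maxit = 200L)
    state$evals <- state$evals + 1L
    if (!ft$ok) return(1e10)
    state$beta <- ft$beta
    v <- laplace_ml(design, ft, ld, lam)
    if (!is.finite(v)) 1e10 else -v
  }
  grid_used <- FALSE
  opt <- NULL
  if (q == 1L) {
    opt <- tryCatch({
      o <- stats::optimize(negml, interval = c(-15, 15), tol = 1e-3)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    }, error = function(e) NULL)
  } else {
    for (i in seq_len(nrow(starts))) {
      oi <- tryCatch(
        stats::optim(starts[i, ], negml, method = "Nelder-Mead",
                     control = list(reltol = reltol, maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(oi) && is.finite(oi$value) &&
          (is.null(opt) || oi$value < opt$value)) opt <- oi
    }
  }
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    ## coarse grid fallback
    grid_used <- TRUE
    gr <- seq(-8, 10, by = 3)
    grid <- as.matrix(do.call(expand.grid, rep(list(gr), q)))
    vals <- apply(grid, 1L, negml)
    opt <- list(par = grid[which.min(vals), ], value = min(vals),
                convergence = 1L)
  }
  rho <- pmin(pmax(opt$par, -18), 18)
  lam <- stats::setNames(as.list(exp(rho)), bnames)
  ld <- lambda_diag(design, lam)
  ft <- pirls(design$X, design$y, ld, beta = state$beta, maxit = 200L)
  finish_fit(design, ft, ld, lam,
             optimizer = list(rho = rho, evals = state$evals,
                              convergence = opt$convergence,
                              grid_fallback = grid_used,
                              criterion = -opt$value))
}
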