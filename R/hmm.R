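## Two-state hidden Markov model with Bernoulli emissions for per-plant
## monthly fruit series, used to impute missing months.  All recursions are
## scaled (normalized forward/backward variables); missing observations
## contribute a unit emission likelihood.

hmm_check <- function(model) {
  stopifnot(is.list(model),
            length(model$initial) == 2L, length(model$emission) == 2L,
            all(dim(model$transition) == c(2L, 2L)))
  if (abs(sum(model$initial) - 1) > 1e-8 ||
      any(abs(rowSums(model$transition) - 1) > 1e-8) ||
      any(unlist(model[c("initial", "transition", "emission")]) < -1e-12) ||
      any(unlist(model[c("initial", "transition", "emission")]) > 1 + 1e-12))
    stop("invalid HMM: probabilities must be in [0,1] and rows sum to 1")
  invisible(model)
}

## emission likelihood matrix: T x 2, rows for missing observations are 1
hmm_emission_lik <- function(series, emission) {
  Tn <- length(series)
  E <- matrix(1, Tn, 2L)
  obs <- !is.na(series)
  E[obs, 1L] <- ifelse(series[obs] == 1, emission[1L], 1 - emission[1L])
  E[obs, 2L] <- ifelse(series[obs] == 1, emission[2L], 1 - emission[2L])
  E
}

## scaled forward-backward; returns state posteriors, pairwise posteriors and
## the log-likelihood of the observed (non-missing) data
hmm_forward_backward <- function(series, model) {
  hmm_check(model)
  Tn <- length(series)
  E <- hmm_emission_lik(series, model$emission)
  P <- model$transition
  alpha <- matrix(0, Tn, 2L)
  beta <- matrix(0, Tn, 2L)
  cvec <- numeric(Tn)
  a <- model$initial * E[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  for (t in 2L:Tn) {
    a <- drop(alpha[t - 1L, ] %*% P) * E[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta[Tn, ] <- 1
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    beta[t, ] <- drop(P %*% (E[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  ## expected transition counts (summed over time)
  xi <- matrix(0, 2L, 2L)
  if (Tn > 1L) for (t in seq_len(Tn - 1L)) {
    M <- outer(alpha[t, ], E[t + 1L, ] * beta[t + 1L, ]) * P / cvec[t + 1L]
    xi <- xi + M
  }
  list(gamma = gamma, xi = xi, log_lik = sum(log(cvec)))
}

#' Fit a two-state Bernoulli hidden Markov model to one fruit series
#'
#' Baum--Welch (EM) estimation with missing entries contributing a unit
#' emission likelihood. Initialization is fixed (initial probabilities
#' (0.5, 0.5), self-transitions 0.7, emission probabilities 0.25 and 0.75)
#' so the fit is deterministic. The observed-data log-likelihood is
#' non-decreasing across iterations.
#'
#' @param series Vector over consecutive months with values 0, 1 or `NA`.
#' @param max_iter,tol EM iteration cap and log-likelihood increment
#'   stopping tolerance.
#' @return A list of class `"hmm_model"`: `initial`, `transition` (2x2 row
#'   stochastic), `emission` (per-state probability of fruit = 1),
#'   `log_lik`, `log_lik_trace`, `iterations`, `degenerate` flag.
#' @export
fit_hmm <- function(series, max_iter = 500L, tol = 1e-6) {
  if (length(series) < 4L) stop("series too short (need length >= 4)")
  obs <- series[!is.na(series)]
  if (!length(obs)) stop("all-missing series: nothing to fit")
  if (!all(obs %in% c(0, 1))) stop("series values must be 0, 1 or NA")
  if (all(obs == obs[1L])) {
    ## degenerate constant series: pin emissions near the boundary
    p1 <- if (obs[1L] == 1) 1 - 1e-6 else 1e-6
    model <- list(initial = c(0.5, 0.5),
                  transition = matrix(0.5, 2L, 2L),
                  emission = c(p1, p1),
                  log_lik = length(obs) * log(1 - 1e-6),
                  log_lik_trace = numeric(0), iterations = 0L,
                  degenerate = TRUE)
    class(model) <- "hmm_model"
    return(model)
  }
  model <- list(initial = c(0.5, 0.5),
                transition = matrix(c(0.7, 0.3, 0.3, 0.7), 2L, byrow = TRUE),
                emission = c(0.25, 0.75))
  trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    fb <- hmm_forward_backward(series, model)
    trace <- c(trace, fb$log_lik)
    ## M step
    obs_idx <- !is.na(series)
    gobs <- fb$gamma[obs_idx, , drop = FALSE]
    yobs <- series[obs_idx]
    em <- pmin(pmax(colSums(gobs * yobs) / colSums(gobs), 1e-8), 1 - 1e-8)
    trans <- fb$xi / pmax(rowSums(fb$xi), 1e-300)
    model <- list(initial = fb$gamma[1L, ],
                  transition = trans, emission = em)
    if (fb$log_lik - ll_old < tol && it > 1L) break
    ll_old <- fb$log_lik
  }
  fb <- hmm_forward_backward(series, model)
  model$log_lik <- fb$log_lik
  model$log_lik_trace <- trace
  model$iterations <- it
  model$degenerate <- FALSE
  class(model) <- "hmm_model"
  model
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("Two-state Bernoulli HMM",
      if (x$degenerate) "(degenerate constant series)" else "", "\n")
  cat(sprintf("  emission P(fruit=1 | state): %.3f / %.3f\n",
              x$emission[1], x$emission[2]))
  cat(sprintf("  self-transitions: %.3f / %.3f, logLik %.3f\n",
              x$transition[1, 1], x$transition[2, 2], x$log_lik))
  invisible(x)
}

#' Posterior probability of fruit presence at every month
#'
#' Forward--backward smoothing: the emission-weighted posterior
#' \eqn{P(y_t = 1 \mid \mathrm{observed})} at every month, marginalizing over
#' the hidden state.
#'
#' @param series Vector with values 0, 1 or `NA`.
#' @param model A fitted [fit_hmm()] model.
#' @return Numeric vector of posterior fruit probabilities.
#' @export
hmm_posterior <- function(series, model) {
  hmm_check(model)
  fb <- hmm_forward_backward(series, model)
  post <- drop(fb$gamma %*% model$emission)
  obs <- !is.na(series)
  post[obs] <- series[obs]   # observed months are known exactly
  post
}

#' Impute missing months of one fruit series
#'
#' Replaces each missing entry by the indicator that its posterior fruit
#' probability exceeds one half (ties resolved by carrying the previous
#' month's completed value forward; a tie at the first month takes the
#' posterior's rounding). Observed entries are returned unchanged.
#'
#' @param series Vector with values 0, 1 or `NA`.
#' @param model A fitted [fit_hmm()] model (default: fit to `series`).
#' @return Completed 0/1 vector with attribute `posterior` (the posterior
#'   fruit probability at every month).
#' @export
smooth_impute <- function(series, model = fit_hmm(series)) {
  post <- hmm_posterior(series, model)
  out <- series
  for (t in seq_along(series)) {
    if (!is.na(series[t])) next
    p <- post[t]
    out[t] <- if (p > 0.5) 1
    else if (p < 0.5) 0
    else if (t > 1L) out[t - 1L]
    else as.numeric(p >= 0.5)
  }
  attr(out, "posterior") <- post
  out
}

#' Impute all missing entries of a phenology panel
#'
#' Fits a two-state Bernoulli HMM to each plant's monthly series separately
#' and fills the missing months with thresholded forward--backward smoothed
#' estimates.
#'
#' @param panel A phenology panel (possibly with `NA` status).
#' @return The completed panel; `attr(, "imputation_mask")` is a data frame
#'   (plant_id, month_index, imputed_value, posterior) describing every
#'   filled entry.
#' @export
impute_panel <- function(panel) {
  panel <- validate_panel(panel)
  out <- panel
  masks <- list()
  for (pid in unique(panel$plant_id)) {
    idx <- which(panel$plant_id == pid)
    ser <- panel$status[idx]
    if (!anyNA(ser)) next
    comp <- smooth_impute(ser)
    miss <- which(is.na(ser))
    masks[[length(masks) + 1L]] <- data.frame(
      plant_id = pid, month_index = panel$month_index[idx][miss],
      imputed_value = as.numeric(comp[miss]),
      posterior = attr(comp, "posterior")[miss])
    out$status[idx] <- as.numeric(comp)
  }
  attr(out, "imputation_mask") <- if (length(masks)) {
    do.call(rbind, masks)
  } else {
    data.frame(plant_id = character(0), month_index = integer(0),
               imputed_value = numeric(0), posterior = numeric(0))
  }
  out
}
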