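## Independent oracles used across the test files.  These deliberately share
## no code with the package internals.

## Unpenalized logistic regression by straight Newton-Raphson.
newton_logistic <- function(X, y, maxit = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- crossprod(X, y - mu)
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  list(beta = unname(drop(beta)),
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

## Penalized IRLS in the *original* (un-reparameterized) basis: intercept
## plus one centered smooth block with penalty lambda * S.
pirls_original_basis <- function(Xs, S, y, lambda, maxit = 500) {
  X <- cbind(1, Xs)
  P <- matrix(0, ncol(X), ncol(X))
  P[-1, -1] <- lambda * S
  mu <- rep(mean(y), length(y))
  eta <- log(mu / (1 - mu))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X * sqrt(w)) + P
    beta_new <- solve(A, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-11) { beta <- beta_new; break }
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
  }
  eta <- drop(X %*% beta)
  list(beta = drop(beta), fitted = 1 / (1 + exp(-eta)))
}

## Brute-force HMM posteriors by enumerating all 2^T hidden state paths.
hmm_enumerate <- function(series, model) {
  Tn <- length(series)
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  lik <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    st <- paths[i, ]
    l <- model$initial[st[1]]
    if (Tn > 1) for (t in 2:Tn) l <- l * model$transition[st[t - 1], st[t]]
    for (t in 1:Tn) {
      if (!is.na(series[t])) {
        e <- model$emission[st[t]]
        l <- l * ifelse(series[t] == 1, e, 1 - e)
      }
    }
    lik[i] <- l
  }
  tot <- sum(lik)
  gamma <- matrix(0, Tn, 2)
  for (t in 1:Tn) for (s in 1:2) gamma[t, s] <- sum(lik[paths[, t] == s]) / tot
  list(gamma = gamma, log_lik = log(tot))
}

## Quick single-species panel with independent Bernoulli draws.
quick_panel <- function(eta_fun, n_plants = 10, n_months = 60, seed = 1,
                        start_month = 1) {
  set.seed(seed)
  t <- rep(seq_len(n_months), times = n_plants)
  cal <- ((start_month - 1 + t - 1) %% 12) + 1
  data.frame(plant_id = rep(sprintf("p%02d", seq_len(n_plants)),
                            each = n_months),
             species = "sp", month_index = t, calendar_month = cal,
             status = rbinom(n_plants * n_months, 1,
                             1 / (1 + exp(-eta_fun(t, cal)))))
}
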