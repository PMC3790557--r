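## Wald chi-square statistic beta' V^- beta using a rank-r pseudoinverse of V.
wald_chisq <- function(beta, V, rank) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  tol <- max(eg$values, 0) * 1e-10
  usable <- sum(eg$values > tol)
  r <- min(rank, usable)
  r <- max(r, 1L)
  proj <- crossprod(eg$vectors[, seq_len(r), drop = FALSE], beta)
  stat <- sum(proj^2 / eg$values[seq_len(r)])
  list(statistic = stat, rank = r)
}

## posterior mean and covariance of a smooth's coefficients in the original
## centered-basis parameterization
smooth_posterior <- function(fit, term) {
  sm <- fit$design$smooths[[term]]
  if (is.null(sm)) {
    ## allow matching by covariate name
    hit <- vapply(fit$design$smooths,
                  function(z) z$spec$covariate == term, TRUE)
    if (sum(hit) != 1L)
      stop("smooth term '", term, "' not found in the model")
    sm <- fit$design$smooths[[which(hit)]]
  }
  beta <- drop(sm$Tmap %*% fit$coefficients[sm$cols])
  V <- sm$Tmap %*% fit$Vp[sm$cols, sm$cols, drop = FALSE] %*% t(sm$Tmap)
  list(sm = sm, beta = beta, V = (V + t(V)) / 2,
       edf = fit$edf_smooth[[sm$label]])
}

#' Wald chi-square test of a smooth term
#'
#' Tests whether a smooth function is zero using the quadratic form
#' \eqn{\hat\beta_j' V_j^{-} \hat\beta_j}, where \eqn{V_j} is the Bayesian
#' posterior covariance of the term's coefficients and the pseudoinverse is
#' truncated at rank `r`, the term's effective degrees of freedom rounded to
#' the nearest integer (at least 1). The P-value is the upper tail of a
#' chi-square with `r` degrees of freedom; the fractional edf is reported
#' alongside the integer rank actually used.
#'
#' @param fit A [pgamm()] fit.
#' @param term Smooth term label (e.g. `"s(month_index)"`) or its covariate
#'   name.
#' @return An object of class `"smooth_test"` with `statistic`, `rank_r`,
#'   `edf`, `p_value`, `term_name`.
#' @export
smooth_test <- function(fit, term) {
  stopifnot(inherits(fit, "pgamm"))
  post <- smooth_posterior(fit, term)
  r <- max(1L, min(length(post$beta), as.integer(round(post$edf))))
  w <- wald_chisq(post$beta, post$V, r)
  structure(list(statistic = w$statistic, rank_r = w$rank, edf = post$edf,
                 p_value = stats::pchisq(w$statistic, w$rank,
                                         lower.tail = FALSE),
                 term_name = post$sm$label),
            class = "smooth_test")
}

#' @export
print.smooth_test <- function(x, ...) {
  cat(sprintf("Wald test of %s: chi-sq = %.3f, rank = %d (edf %.2f), p = %.4g\n",
              x$term_name, x$statistic, x$rank_r, x$edf, x$p_value))
  invisible(x)
}

#' Pointwise Bayesian credible band of a smooth term
#'
#' Computes the fitted smooth and a pointwise `level` credible band,
#' \eqn{\hat s(t) \pm z_{(1+level)/2}\, \mathrm{SD}(t)}, on the linear
#' predictor scale, from the posterior coefficient covariance implied by the
#' roughness prior.
#'
#' @param fit A [pgamm()] fit.
#' @param term Smooth term label or covariate name.
#' @param eval_points Covariate values at which to evaluate the band.
#' @param level Credible level in (0, 1); default 0.95.
#' @return An object of class `"credible_band"`: list with `eval_points`,
#'   `fit`, `lower`, `upper`, `level`, `term`.
#' @export
credible_band <- function(fit, term, eval_points, level = 0.95) {
  stopifnot(inherits(fit, "pgamm"))
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("'level' must be in (0, 1)")
  post <- smooth_posterior(fit, term)
  Xn <- basis_rows(post$sm$expansion, eval_points)
  est <- drop(Xn %*% post$beta)
  se <- sqrt(pmax(0, rowSums((Xn %*% post$V) * Xn)))
  z <- stats::qnorm((1 + level) / 2)
  structure(list(eval_points = eval_points, fit = est,
                 lower = est - z * se, upper = est + z * se,
                 level = level, term = post$sm$label),
            class = "credible_band")
}

#' @export
print.credible_band <- function(x, ...) {
  cat(sprintf("%g%% credible band for %s at %d points\n",
              100 * x$level, x$term, length(x$eval_points)))
  invisible(x)
}

#' @export
as.data.frame.credible_band <- function(x, ...) {
  data.frame(eval_point = x$eval_points, fit = x$fit,
             lower = x$lower, upper = x$upper)
}

## structural complexity: non-intercept fixed coefficients (parametric slopes
## and smooth null spaces) plus one per variance/smoothing component
structural_df <- function(fit) {
  d <- fit$design
  (length(d$par_cols) - 1L) +
    sum(vapply(d$smooths, function(sm) sm$n_null, 0L)) +
    length(d$smooths) +
    (!is.null(d$re))
}

#' Likelihood ratio test between nested additive models
#'
#' Compares two maximum-likelihood fits of nested model structures using
#' twice the difference in Laplace-approximate marginal log-likelihoods,
#' referred to a chi-square distribution. Degrees of freedom follow the
#' structural rule: each model's complexity counts its non-intercept fixed
#' coefficients (parametric slopes and smooth-term null-space dimensions,
#' e.g. the linear component of a cubic trend smooth) plus one per
#' smoothing/variance component; the test df is the difference in
#' complexity. Terms shared by both models (lag, random intercepts) cancel.
#' The usual boundary caveat for variance-component likelihood ratio tests
#' applies; the plain chi-square reference is used and documented.
#'
#' @param full,nested `"pgamm"` fits of the full and reduced structure on
#'   identical data.
#' @return A `"model_comparison"` list with `statistic`, `df`, `p_value`, and
#'   the two log-likelihoods.
#' @export
lrt <- function(full, nested) {
  stopifnot(inherits(full, "pgamm"), inherits(nested, "pgamm"))
  if (full$n_obs != nested$n_obs)
    stop("models were not fitted to the same data (different n)")
  df <- structural_df(full) - structural_df(nested)
  if (df < 0) stop("'full' is less complex than 'nested'; swap the arguments")
  stat <- 2 * (full$log_lik - nested$log_lik)
  flagged <- FALSE
  if (stat < 0) {
    if (stat > -1e-6) stat <- 0 else flagged <- TRUE
  }
  p <- if (df == 0L) {
    if (abs(stat) < 1e-6) 1 else NA_real_
  } else stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
  structure(list(full_label = attr(full, "label") %||% "full",
                 nested_label = attr(nested, "label") %||% "nested",
                 statistic = max(stat, 0), df = df, p_value = p,
                 log_lik_full = full$log_lik,
                 log_lik_nested = nested$log_lik,
                 negative_flag = flagged),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: chi-sq = %.3f, df = %d, p = %.4g%s\n",
              x$full_label, x$nested_label, x$statistic, x$df, x$p_value,
              if (x$negative_flag) "  [negative statistic flagged]" else ""))
  invisible(x)
}

#' @export
anova.pgamm <- function(object, ..., test = "LRT") {
  others <- list(...)
  if (!length(others) || !inherits(others[[1]], "pgamm"))
    stop("supply two nested pgamm fits: anova(full, nested)")
  lrt(object, others[[1]])
}
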