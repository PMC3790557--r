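#' Smooth term marker for model formulas
#'
#' Used inside a [pgamm()] formula to declare a penalized smooth of one
#' covariate, e.g. `status ~ s(month_index, k = 10) + s(calendar_month,
#' k = 8, bs = "cc")`. Not intended to be called directly.
#'
#' @param x Covariate (bare name).
#' @param k Maximum basis dimension.
#' @param bs `"cr"` or `"cc"`.
#' @param period Period for `bs = "cc"` (default 12 calendar months).
#' @param knots Optional explicit knots.
#' @return A marker list; only meaningful inside a formula.
#' @export
s <- function(x, k = 10, bs = "cr", period = 12, knots = NULL) {
  list(var = deparse(substitute(x)), k = k, bs = bs, period = period,
       knots = knots)
}

parse_smooth_label <- function(label) {
  expr <- str2lang(label)
  cl <- match.call(s, expr)
  args <- as.list(cl)[-1]
  var <- deparse(args$x)
  k <- if (is.null(args$k)) 10 else eval(args$k)
  bs <- if (is.null(args$bs)) "cr" else eval(args$bs)
  period <- if (is.null(args$period)) 12 else eval(args$period)
  knots <- if (is.null(args$knots)) NULL else eval(args$knots)
  smooth_spec(var, k = k, bs = bs,
              period = if (bs == "cc") period else NULL, knots = knots)
}

#' Assemble the penalized design for a binomial additive mixed model
#'
#' Parses a formula with optional [s()] smooth terms, expands each smooth into
#' its centered basis via [build_basis()], and reparameterizes every smooth
#' into an unpenalized null-space part plus an identity-penalized range part
#' (the mixed-model representation: eigenvectors of the roughness penalty,
#' scaled by inverse root eigenvalues). Optional per-group random intercepts
#' enter as one further identity-penalized block, so a single smoothing
#' parameter vector (one \eqn{\lambda} per smooth, plus
#' \eqn{\lambda_{re} = 1/\sigma^2} for the random intercepts) governs all
#' shrinkage.
#'
#' @param formula Model formula; left side is the 0/1 response, right side
#'   parametric terms and/or [s()] smooths.
#' @param data A data frame containing all variables.
#' @param random Optional one-sided formula naming the grouping factor for
#'   random intercepts, e.g. `~ plant_id`; at least two groups required.
#' @return A `"pgamm_design"` list used by [fit_penalized()] and
#'   [select_lambda_ml()].
#' @export
build_design <- function(formula, data, random = NULL) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  tf <- stats::terms(formula, specials = "s", data = data)
  if (attr(tf, "response") != 1L) stop("formula needs a response")
  resp_name <- deparse(attr(tf, "variables")[[2]])
  y <- data[[resp_name]]
  if (is.null(y)) stop("response '", resp_name, "' not found in data")
  if (any(is.na(y))) stop("response contains missing values; impute first")
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  y <- as.numeric(y)
  n <- length(y)

  labels <- attr(tf, "term.labels")
  is_sm <- grepl("^s\\(", labels)
  par_labels <- labels[!is_sm]
  sm_labels <- labels[is_sm]

  ## parametric block (always includes the intercept)
  Xpar <- if (length(par_labels)) {
    stats::model.matrix(stats::reformulate(par_labels, intercept = TRUE), data)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (nrow(Xpar) != n) stop("missing values in parametric covariates")

  cols <- list()
  Xlist <- list(Xpar)
  col_at <- ncol(Xpar)
  par_cols <- seq_len(ncol(Xpar))

  smooths <- list()
  blocks <- list()
  for (lab in sm_labels) {
    spec <- parse_smooth_label(lab)
    xv <- data[[spec$covariate]]
    if (is.null(xv)) stop("covariate '", spec$covariate, "' not found in data")
    bx <- build_basis(spec, xv)
    S <- bx$penalty
    eg <- eigen(S, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-8
    r <- sum(pos)
    U0 <- eg$vectors[, !pos, drop = FALSE]
    Up <- eg$vectors[, pos, drop = FALSE]
    scl <- 1 / sqrt(eg$values[pos])
    Xnull <- bx$design %*% U0
    Xrange <- bx$design %*% Up %*% diag(scl, r)
    Tmap <- cbind(U0, Up %*% diag(scl, r))  # original coefs = Tmap %*% (null, range)
    n0 <- ncol(U0)
    cols_null <- if (n0) col_at + seq_len(n0) else integer(0)
    cols_range <- col_at + n0 + seq_len(r)
    col_at <- col_at + n0 + r
    term_id <- paste0("s(", spec$covariate, ")")
    if (n0) colnames(Xnull) <- paste0(term_id, ".null", seq_len(n0))
    colnames(Xrange) <- paste0(term_id, ".", seq_len(r))
    Xlist <- c(Xlist, if (n0) list(Xnull), list(Xrange))
    smooths[[term_id]] <- list(label = term_id, spec = spec, expansion = bx,
                               cols = c(cols_null, cols_range), Tmap = Tmap,
                               n_null = n0, rank = r)
    blocks[[term_id]] <- list(name = term_id, cols = cols_range, rank = r,
                              type = "smooth")
  }

  re <- NULL
  if (!is.null(random)) {
    stopifnot(inherits(random, "formula"))
    gvar <- all.vars(random)
    if (length(gvar) != 1L) stop("'random' must name exactly one grouping factor")
    g <- factor(data[[gvar]])
    if (nlevels(g) < 2L)
      stop("random intercepts need at least two groups ('", gvar,
           "' has one); use a fixed intercept instead")
    Zre <- stats::model.matrix(~ 0 + g)
    colnames(Zre) <- paste0("re.", levels(g))
    cols_re <- col_at + seq_len(ncol(Zre))
    col_at <- col_at + ncol(Zre)
    Xlist <- c(Xlist, list(Zre))
    re <- list(label = paste0("re(", gvar, ")"), var = gvar,
               levels = levels(g), cols = cols_re, groups = g)
    blocks[[re$label]] <- list(name = re$label, cols = cols_re,
                               rank = ncol(Zre), type = "re")
  }

  X <- do.call(cbind, Xlist)
  structure(list(X = X, y = y, n = n, p = ncol(X),
                 par_cols = par_cols, par_labels = colnames(Xpar),
                 smooths = smooths, blocks = blocks, re = re,
                 formula = formula, resp_name = resp_name),
            class = "pgamm_design")
}

#' @export
print.pgamm_design <- function(x, ...) {
  cat(sprintf("pgamm design: n = %d, p = %d (%d parametric, %d smooth terms%s)\n",
              x$n, x$p, length(x$par_cols), length(x$smooths),
              if (!is.null(x$re)) sprintf(", %d random intercepts",
                                          length(x$re$cols)) else ""))
  invisible(x)
}

## diagonal of the total penalty for a given lambda vector (named by block)
lambda_diag <- function(design, lambdas) {
  d <- numeric(design$p)
  for (b in design$blocks) {
    lam <- lambdas[[b$name]]
    if (is.null(lam) || is.na(lam)) stop("no smoothing parameter for ", b$name)
    if (lam < 0) stop("negative smoothing parameter for ", b$name)
    d[b$cols] <- lam
  }
  d
}
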