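#' Declare a penalized regression spline term
#'
#' Describes a smooth term before any data are seen: the covariate it applies
#' to, the kind of basis (natural cubic or cyclic cubic regression spline),
#' the maximum basis dimension `k`, and for cyclic terms the period.
#'
#' @param covariate Name of the covariate (character scalar).
#' @param k Maximum basis dimension (number of knots); at least 3.
#' @param bs Basis kind: `"cr"` (natural cubic regression spline) or `"cc"`
#'   (cyclic cubic regression spline).
#' @param period Period of the cyclic basis (e.g. 12 for calendar months);
#'   required and positive for `bs = "cc"`, ignored otherwise.
#' @param knots Optional strictly increasing knot vector of length `k`. For a
#'   cyclic basis the knots must span exactly one period
#'   (`knots[k] - knots[1] == period`). If omitted, knots are placed evenly
#'   over the observed covariate range (`"cr"`) or over `[0, period]`
#'   (`"cc"`).
#' @return An object of class `"smooth_spec"`.
#' @seealso [build_basis()], [evaluate_smooth()]
#' @export
#' @examples
#' smooth_spec("month_index", k = 10, bs = "cr")
#' smooth_spec("calendar_month", k = 8, bs = "cc", period = 12)
smooth_spec <- function(covariate, k, bs = c("cr", "cc"), period = NULL,
                        knots = NULL) {
  bs <- match.arg(bs)
  stopifnot(is.character(covariate), length(covariate) == 1L)
  if (!is.numeric(k) || length(k) != 1L || k < 3)
    stop("'k' (maximum basis dimension) must be a single number >= 3")
  k <- as.integer(k)
  if (bs == "cc") {
    if (is.null(period) || !is.numeric(period) || period <= 0)
      stop("a cyclic basis requires a positive 'period'")
  } else {
    period <- NULL
  }
  if (!is.null(knots)) {
    if (length(knots) != k)
      stop("'knots' must have length k = ", k)
    if (any(!is.finite(knots)) || any(diff(knots) <= 0))
      stop("'knots' must be finite and strictly increasing")
    if (bs == "cc" && abs((knots[k] - knots[1]) - period) > 1e-8 * period)
      stop("cyclic knots must span exactly one period")
  }
  structure(list(covariate = covariate, k = k, bs = bs, period = period,
                 knots = knots),
            class = "smooth_spec")
}

#' @export
print.smooth_spec <- function(x, ...) {
  cat(sprintf("Smooth term %s(%s): k = %d%s\n",
              x$bs, x$covariate, x$k,
              if (x$bs == "cc") sprintf(", period = %g", x$period) else ""))
  invisible(x)
}

## Natural cubic regression spline in the "function values at knots"
## parameterisation.  With knots x_1 < ... < x_k and natural end conditions
## (f'' = 0 at both boundary knots), the second derivatives at interior knots
## are F %*% beta with F = B^{-1} D, where B and D are the classical banded
## matrices of the tridiagonal interpolation system.  The roughness penalty
## int f''(x)^2 dx is then beta' D' B^{-1} D beta, exact for this family.
cr_matrices <- function(kn) {
  k <- length(kn)
  h <- diff(kn)
  B <- matrix(0, k - 2L, k - 2L)
  D <- matrix(0, k - 2L, k)
  for (i in seq_len(k - 2L)) {
    D[i, i]      <- 1 / h[i]
    D[i, i + 1L] <- -1 / h[i] - 1 / h[i + 1L]
    D[i, i + 2L] <- 1 / h[i + 1L]
    B[i, i] <- (h[i] + h[i + 1L]) / 3
    if (i < k - 2L) {
      B[i, i + 1L] <- h[i + 1L] / 6
      B[i + 1L, i] <- h[i + 1L] / 6
    }
  }
  BiD <- solve(B, D)
  Fp <- rbind(0, BiD, 0)              # 2nd derivatives at all k knots
  S <- crossprod(D, BiD)
  list(Fp = Fp, S = (S + t(S)) / 2, h = h)
}

## Design rows of the natural cubic spline basis at arbitrary x.  Outside the
## knot range the natural spline continues linearly; callers that care warn.
cr_eval <- function(x, kn, mats = cr_matrices(kn)) {
  k <- length(kn)
  h <- mats$h
  Fp <- mats$Fp
  n <- length(x)
  X <- matrix(0, n, k)
  left <- x < kn[1]
  right <- x > kn[k]
  inside <- !(left | right)
  if (any(inside)) {
    xi <- x[inside]
    j <- pmin(pmax(findInterval(xi, kn), 1L), k - 1L)
    hj <- h[j]
    dxm <- kn[j + 1L] - xi
    dxp <- xi - kn[j]
    am <- dxm / hj
    ap <- dxp / hj
    cm <- (dxm^3 / hj - hj * dxm) / 6
    cp <- (dxp^3 / hj - hj * dxp) / 6
    rows <- which(inside)
    Xi <- cm * Fp[j, , drop = FALSE] + cp * Fp[j + 1L, , drop = FALSE]
    Xi[cbind(seq_along(j), j)] <- Xi[cbind(seq_along(j), j)] + am
    Xi[cbind(seq_along(j), j + 1L)] <- Xi[cbind(seq_along(j), j + 1L)] + ap
    X[rows, ] <- Xi
  }
  if (any(left)) {
    ## value and slope at the first knot
    v <- numeric(k); v[1] <- 1
    d <- numeric(k); d[1] <- -1 / h[1]; d[2] <- 1 / h[1]
    d <- d - h[1] / 3 * Fp[1, ] - h[1] / 6 * Fp[2, ]
    X[left, ] <- outer(rep(1, sum(left)), v) + outer(x[left] - kn[1], d)
  }
  if (any(right)) {
    v <- numeric(k); v[k] <- 1
    d <- numeric(k); d[k - 1L] <- -1 / h[k - 1L]; d[k] <- 1 / h[k - 1L]
    d <- d + h[k - 1L] / 6 * Fp[k - 1L, ] + h[k - 1L] / 3 * Fp[k, ]
    X[right, ] <- outer(rep(1, sum(right)), v) + outer(x[right] - kn[k], d)
  }
  X
}

## Cyclic cubic regression spline: k knots spanning one period, k-1 free
## function values (f(x_k) = f(x_1)).  Continuity of f' at every knot gives a
## cyclic tridiagonal system B delta = D beta for the second derivatives; the
## penalty is again beta' D' B^{-1} D beta.
cc_matrices <- function(kn) {
  k <- length(kn)
  m <- k - 1L
  h <- diff(kn)                       # lengths of the m intervals
  B <- matrix(0, m, m)
  D <- matrix(0, m, m)
  for (j in seq_len(m)) {
    jm <- if (j == 1L) m else j - 1L
    jp <- if (j == m) 1L else j + 1L
    hm <- h[jm]
    hj <- h[j]
    B[j, j] <- B[j, j] + (hm + hj) / 3
    B[j, jp] <- B[j, jp] + hj / 6
    B[j, jm] <- B[j, jm] + hm / 6
    D[j, j] <- D[j, j] - 1 / hm - 1 / hj
    D[j, jp] <- D[j, jp] + 1 / hj
    D[j, jm] <- D[j, jm] + 1 / hm
  }
  BiD <- solve(B, D)                  # 2nd derivatives at knots 1..m
  S <- crossprod(D, BiD)
  list(Fp = BiD, S = (S + t(S)) / 2, h = h)
}

cc_eval <- function(x, kn, mats = cc_matrices(kn)) {
  k <- length(kn)
  m <- k - 1L
  period <- kn[k] - kn[1]
  h <- mats$h
  Fp <- mats$Fp
  xr <- kn[1] + (x - kn[1]) %% period
  j <- pmin(pmax(findInterval(xr, kn), 1L), m)
  jp <- ifelse(j == m, 1L, j + 1L)
  hj <- h[j]
  dxm <- kn[j + 1L] - xr
  dxp <- xr - kn[j]
  am <- dxm / hj
  ap <- dxp / hj
  cm <- (dxm^3 / hj - hj * dxm) / 6
  cp <- (dxp^3 / hj - hj * dxp) / 6
  X <- cm * Fp[j, , drop = FALSE] + cp * Fp[jp, , drop = FALSE]
  X[cbind(seq_along(j), j)] <- X[cbind(seq_along(j), j)] + am
  X[cbind(seq_along(j), jp)] <- X[cbind(seq_along(j), jp)] + ap
  X
}

#' Realize a smooth-term basis on covariate data
#'
#' Evaluates the regression spline basis of a [smooth_spec()] at the fitting
#' covariate values, applies the sum-to-zero identifiability constraint (each
#' basis column sums to zero over the fitting data, the constant being
#' absorbed by the model intercept), and returns the centered design block
#' together with the quadratic roughness penalty (integrated squared second
#' derivative, exact in closed form for these spline families).
#'
#' A natural cubic basis with `k` knots yields `k - 1` centered columns whose
#' penalty has a one-dimensional null space (the centered linear function); a
#' cyclic basis yields `k - 2` centered columns (one dimension lost to
#' periodicity, one to centering) with a full-rank penalty.
#'
#' @param spec A [smooth_spec()].
#' @param x Covariate values of the fitting data (finite numeric vector).
#' @return An object of class `"basis_expansion"` with elements
#'   `design` (n x p centered design block), `penalty` (p x p symmetric
#'   positive semi-definite), `null_space_dim`, `knots`, `Z` (the constraint
#'   absorption matrix), and `spec`.
#' @export
#' @examples
#' bx <- build_basis(smooth_spec("t", k = 10), x = 1:120)
#' dim(bx$design)        # 120 x 9
#' round(colSums(bx$design), 10)
build_basis <- function(spec, x) {
  stopifnot(inherits(spec, "smooth_spec"))
  if (length(x) == 0L) stop("covariate values must be non-empty")
  if (any(!is.finite(x))) stop("non-finite covariate values")
  k <- spec$k
  if (spec$bs == "cc") {
    xd <- (x - min(x)) %% spec$period
    ndist <- length(unique(round(xd, 10)))
    if (ndist < k - 1L)
      stop("degenerate basis: fewer distinct covariate values (", ndist,
           " after modular reduction) than free basis functions (", k - 1L, ")")
    kn <- if (is.null(spec$knots)) seq(0, spec$period, length.out = k) else spec$knots
    mats <- cc_matrices(kn)
    Xraw <- cc_eval(x, kn, mats)
  } else {
    ndist <- length(unique(x))
    if (ndist < k)
      stop("degenerate basis: fewer distinct covariate values (", ndist,
           ") than basis dimension (", k, ")")
    kn <- if (is.null(spec$knots)) seq(min(x), max(x), length.out = k) else spec$knots
    mats <- cr_matrices(kn)
    Xraw <- cr_eval(x, kn, mats)
  }
  ## absorb the sum-to-zero constraint: Z spans the null space of colSums(Xraw)
  cs <- colSums(Xraw)
  qr_c <- qr(matrix(cs, ncol = 1L))
  Z <- qr.Q(qr_c, complete = TRUE)[, -1L, drop = FALSE]
  design <- Xraw %*% Z
  S <- crossprod(Z, mats$S %*% Z)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  null_dim <- sum(ev < max(ev, 0) * 1e-8)
  structure(list(spec = spec, knots = kn, mats = mats, Z = Z,
                 design = design, penalty = S, null_space_dim = null_dim,
                 x_range = range(x), n = length(x)),
            class = "basis_expansion")
}

#' @export
print.basis_expansion <- function(x, ...) {
  cat(sprintf("Basis expansion %s(%s): %d x %d centered design, penalty rank %d\n",
              x$spec$bs, x$spec$covariate, nrow(x$design), ncol(x$design),
              ncol(x$design) - x$null_space_dim))
  invisible(x)
}

## Centered basis rows at new covariate values, reusing the fitting-data
## centering transform.  Warns on extrapolation for non-cyclic bases.
basis_rows <- function(expansion, newx, warn_extrapolate = TRUE) {
  stopifnot(inherits(expansion, "basis_expansion"))
  if (any(!is.finite(newx))) stop("non-finite evaluation points")
  if (expansion$spec$bs == "cc") {
    Xraw <- cc_eval(newx, expansion$knots, expansion$mats)
  } else {
    if (warn_extrapolate &&
        (min(newx) < expansion$x_range[1] - 1e-8 ||
         max(newx) > expansion$x_range[2] + 1e-8))
      warning("evaluation outside the training covariate range; ",
              "the spline is extrapolated linearly")
    Xraw <- cr_eval(newx, expansion$knots, expansion$mats)
  }
  Xraw %*% expansion$Z
}

#' Evaluate a fitted smooth on new covariate values
#'
#' Applies the centered basis of `expansion` (with the centering constants of
#' the fitting data) to `new_values` and returns the smooth on the linear
#' predictor scale. At the training covariates this reproduces
#' `expansion$design %*% coefficients` exactly.
#'
#' @param expansion A [build_basis()] result.
#' @param coefficients Coefficient vector, one per centered basis column.
#' @param new_values Covariate values at which to evaluate.
#' @return Numeric vector of smooth values (logit scale).
#' @export
evaluate_smooth <- function(expansion, coefficients, new_values) {
  stopifnot(inherits(expansion, "basis_expansion"))
  if (length(coefficients) != ncol(expansion$design))
    stop("coefficient length (", length(coefficients),
         ") does not match the basis dimension (", ncol(expansion$design), ")")
  drop(basis_rows(expansion, new_values) %*% coefficients)
}
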