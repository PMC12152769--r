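# Penalized cubic B-spline machinery shared by the location models.
#
# A single basis family (cubic B-splines, interior knots at quantiles,
# second-order difference penalty, smoothing parameter by GCV) is used for
# every spline term so that the gam- and ls-flavoured harmonizers differ
# only in their scale model, not in their smoother.

# Build the knot description for a cubic B-spline basis on x.
ps_knots <- function(x, n_knots = 10) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) stop("spline covariate is constant; cannot place knots")
  # equally spaced knots extended beyond the boundary (Eilers-Marx
  # convention): the second-difference penalty then leaves linear
  # functions exactly unpenalized
  h <- (hi - lo) / (n_knots + 1)
  list(boundary = c(lo, hi), interior = lo + h * seq_len(n_knots),
       knots = seq(lo - 3 * h, hi + 3 * h, by = h))
}

# Evaluate the basis with linear extension beyond the training boundary.
ps_eval <- function(kn, x, warn_extrapolation = TRUE) {
  lo <- kn$boundary[1]
  hi <- kn$boundary[2]
  p <- length(kn$knots) - 4L
  B <- matrix(0, length(x), p)
  inside <- x >= lo & x <= hi
  if (any(inside)) {
    B[inside, ] <- splines::splineDesign(kn$knots, x[inside], ord = 4)
  }
  out <- !inside
  if (any(out)) {
    if (warn_extrapolation) {
      warning(sprintf("%d covariate value(s) outside the spline training range [%.4g, %.4g]; using linear extrapolation",
                      sum(out), lo, hi))
    }
    for (b in c(lo, hi)) {
      idx <- which(if (b == lo) x < lo else x > hi)
      if (!length(idx)) next
      B0 <- splines::splineDesign(kn$knots, b, ord = 4)
      B1 <- splines::splineDesign(kn$knots, b, ord = 4, derivs = 1L)
      B[idx, ] <- rep(1, length(idx)) %o% drop(B0) + (x[idx] - b) %o% drop(B1)
    }
  }
  B
}

# Second-order difference penalty for a p-column basis.
ps_penalty <- function(p) {
  D <- diff(diag(p), differences = 2)
  crossprod(D)
}

# Sum-to-zero reparametrization so the spline block excludes the constant
# function (which lives in the intercept / batch columns).
ps_constraint <- function(B) {
  C <- colMeans(B)
  qr.Q(qr(matrix(C, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
}

# Penalized (weighted) least squares with GCV selection of lambda over the
# spline block only.  X = [unpenalized | spline], pen_idx marks spline cols.
ps_solve <- function(X, y, P_full, pen_idx, weights = NULL,
                     lambda = NULL, lambda_grid = 10^seq(-4, 6, length.out = 25)) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  Xw <- X * sqrt(weights)
  yw <- y * sqrt(weights)
  XtX <- crossprod(Xw)
  Xty <- crossprod(Xw, yw)
  fit_at <- function(lam) {
    A <- XtX + lam * P_full
    beta <- tryCatch(solve(A, Xty), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    edf <- sum(diag(solve(A, XtX)))
    fitted <- drop(X %*% beta)
    rss <- sum(weights * (y - fitted)^2)
    list(beta = drop(beta), edf = edf, fitted = fitted,
         gcv = n * rss / (n - edf)^2, rss = rss, lambda = lam)
  }
  if (!any(pen_idx) || !is.null(lambda)) {
    lam <- if (is.null(lambda)) 0 else lambda
    res <- fit_at(lam)
    if (is.null(res)) stop("penalized least-squares system is singular")
    return(res)
  }
  fits <- lapply(lambda_grid, fit_at)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("penalized least-squares system is singular at all smoothing values")
  fits <- fits[ok]
  fits[[which.min(vapply(fits, `[[`, numeric(1), "gcv"))]]
}
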