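#' Validate a covariate frame
#'
#' Covariate frames are plain data frames with an `age` column (strictly
#' positive, days or years post-conception) and a binary `sex` column coded
#' `0` = female (reference) / `1` = male.  Additional numeric columns are
#' carried along and enter the moment models linearly.
#'
#' @param X data frame of covariates.
#' @return `X`, invisibly, after validation.
#' @export
validate_covariates <- function(X) {
  if (!is.data.frame(X)) stop("covariates must be a data frame")
  if (!all(c("age", "sex") %in% names(X))) {
    stop("covariate frame must contain 'age' and 'sex' columns; found: ",
         paste(names(X), collapse = ", "))
  }
  if (anyNA(X)) stop("covariate frame contains missing values; apply listwise deletion first")
  if (any(X$age <= 0)) stop("age must be strictly positive")
  if (!all(X$sex %in% c(0, 1))) stop("sex must be coded 0 (female) / 1 (male)")
  invisible(X)
}

batch_dummies <- function(batch) {
  lv <- levels(batch)
  Bm <- vapply(lv, function(l) as.numeric(batch == l), numeric(length(batch)))
  colnames(Bm) <- paste0("batch:", lv)
  Bm
}

covar_design <- function(X, age_center, age_scale) {
  age_c <- (X$age - age_center) / age_scale
  other <- X[, setdiff(names(X), "age"), drop = FALSE]
  list(age_c = age_c, other = as.matrix(other))
}

#' Fit a covariate model for a feature's location
#'
#' Fits the mean model \eqn{y = \alpha + f(x) + \gamma_{batch} + \epsilon}
#' by (penalized, weighted) least squares.  `spec` controls `f`: a linear
#' age term, a penalized cubic B-spline in age plus a linear sex effect, or
#' the spline plus a sex-varying spline interaction.  When `batch` is
#' supplied, per-batch intercepts are estimated and reported as deviations
#' from their sample-size-weighted mean, so they satisfy
#' \eqn{\sum_i n_i \gamma_i = 0}.
#'
#' @param y numeric response vector (one feature).
#' @param X covariate data frame (see [validate_covariates()]).
#' @param spec one of `"intercept"`, `"linear"`, `"spline"`,
#'   `"spline_interaction"`.
#' @param batch optional factor of batch labels.
#' @param weights optional positive case weights (used by the location-scale
#'   backfit).
#' @param n_knots number of interior knots for spline specs.
#' @param lambda optional fixed smoothing parameter; default is selection by
#'   generalized cross-validation.
#' @return an object of class `location_fit` with coefficients, basis
#'   description, fitted values and residuals.
#' @export
fit_location <- function(y, X, spec = c("spline", "linear", "spline_interaction", "intercept"),
                         batch = NULL, weights = NULL, n_knots = 10, lambda = NULL) {
  spec <- match.arg(spec)
  validate_covariates(X)
  n <- length(y)
  if (n != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(is.finite(y))) stop("y must be finite")
  age_center <- mean(X$age)
  age_scale <- stats::sd(X$age)
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
  d <- covar_design(X, age_center, age_scale)

  if (!is.null(batch)) {
    batch <- droplevels(as.factor(batch))
    Bm <- batch_dummies(batch)
  } else {
    Bm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }

  lin <- d$other
  if (spec == "linear") lin <- cbind(lin, age = d$age_c)
  if (spec == "intercept") lin <- matrix(0, n, 0)
  unpen <- cbind(Bm, lin)

  qr_u <- qr(unpen)
  if (qr_u$rank < ncol(unpen)) {
    bad <- colnames(unpen)[qr_u$pivot[seq(qr_u$rank + 1, ncol(unpen))]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }

  kn <- NULL; Z <- NULL; Zi <- NULL
  pen_blocks <- list()
  Xmat <- unpen
  if (spec %in% c("spline", "spline_interaction")) {
    if (n < n_knots + 6) {
      stop(sprintf("n = %d is too small for %d interior knots; reduce n_knots", n, n_knots))
    }
    kn <- ps_knots(X$age, n_knots)
    B <- ps_eval(kn, X$age, warn_extrapolation = FALSE)
    Z <- ps_constraint(B)
    S <- B %*% Z
    colnames(S) <- paste0("s(age).", seq_len(ncol(S)))
    P <- t(Z) %*% ps_penalty(ncol(B)) %*% Z
    pen_blocks <- c(pen_blocks, list(P))
    Xmat <- cbind(Xmat, S)
    if (spec == "spline_interaction") {
      Si <- S * X$sex
      colnames(Si) <- paste0("s(age):sex.", seq_len(ncol(Si)))
      pen_blocks <- c(pen_blocks, list(P))
      Xmat <- cbind(Xmat, Si)
    }
  }
  if (n < ncol(Xmat) + 2) {
    stop(sprintf("n = %d too small for a %d-column design", n, ncol(Xmat)))
  }

  p <- ncol(Xmat)
  pen_idx <- rep(FALSE, p)
  P_full <- matrix(0, p, p)
  if (length(pen_blocks)) {
    at <- ncol(unpen)
    for (Pb in pen_blocks) {
      idx <- at + seq_len(ncol(Pb))
      P_full[idx, idx] <- Pb
      pen_idx[idx] <- TRUE
      at <- at + ncol(Pb)
    }
  }
  sol <- ps_solve(Xmat, y, P_full, pen_idx, weights = weights, lambda = lambda)
  beta <- sol$beta
  names(beta) <- colnames(Xmat)

  nb <- ncol(Bm)
  if (!is.null(batch)) {
    w <- as.numeric(table(batch)[levels(batch)]) / n
    alpha <- sum(w * beta[seq_len(nb)])
    gamma_raw <- beta[seq_len(nb)] - alpha
    names(gamma_raw) <- levels(batch)
  } else {
    w <- 1
    alpha <- beta[1]
    gamma_raw <- NULL
  }

  fitted <- sol$fitted
  structure(list(
    spec = spec, coefficients = beta, intercept = unname(alpha),
    gamma_raw = gamma_raw, batch_levels = if (is.null(batch)) NULL else levels(batch),
    batch_w = if (is.null(batch)) NULL else stats::setNames(w, levels(batch)),
    n_unpen = ncol(unpen), n_batch_cols = nb,
    covar_names = colnames(lin), knots = kn, Z = Z,
    age_center = age_center, age_scale = age_scale,
    lambda = sol$lambda, edf = sol$edf,
    fitted = fitted, residuals = y - fitted,
    basis_spec = list(spec = spec, n_knots = n_knots,
                      penalty = "second-order difference", selection = "GCV")
  ), class = "location_fit")
}

#' Predict from a location fit
#'
#' @param object a `location_fit`.
#' @param X covariate data frame.
#' @param batch optional factor; when supplied (and the fit was batch-aware)
#'   per-batch intercepts are included, otherwise the batch-free prediction
#'   \eqn{\hat\alpha + \hat f(x)} is returned.
#' @param ... unused.
#' @return numeric vector of predicted locations.
#' @export
predict.location_fit <- function(object, X, batch = NULL, ...) {
  validate_covariates(X)
  d <- covar_design(X, object$age_center, object$age_scale)
  mu <- rep(object$intercept, nrow(X))
  if (!is.null(batch)) {
    if (is.null(object$gamma_raw)) stop("fit was not batch-aware")
    mu <- mu + unname(object$gamma_raw[as.character(batch)])
  }
  beta <- object$coefficients
  nb <- object$n_batch_cols
  lin_names <- object$covar_names
  if (length(lin_names)) {
    vals <- vapply(lin_names, function(nm) {
      if (nm == "age") d$age_c else d$other[, nm]
    }, numeric(nrow(X)))
    vals <- matrix(vals, nrow = nrow(X))
    mu <- mu + drop(vals %*% beta[nb + seq_along(lin_names)])
  }
  if (!is.null(object$knots)) {
    B <- ps_eval(object$knots, X$age)
    S <- B %*% object$Z
    sp_names <- grep("^s\\(age\\)\\.", names(beta))
    mu <- mu + drop(S %*% beta[sp_names])
    int_names <- grep("^s\\(age\\):sex\\.", names(beta))
    if (length(int_names)) {
      mu <- mu + drop((S * X$sex) %*% beta[int_names])
    }
  }
  mu
}

#' Fit a log-linear scale model by maximum likelihood
#'
#' Models residuals as \eqn{N(0, s^2(x))} with
#' \eqn{\log s = \zeta + x^T \eta} (log link guarantees positivity).  When
#' `batch` is supplied the model carries one intercept per batch and no
#' global intercept; the global \eqn{\hat\zeta} is then recovered as the
#' sample-size-weighted mean of the per-batch intercepts and the per-batch
#' log offsets are reported as deviations from it.
#'
#' Fitting is by Fisher scoring with step-halving; the expected information
#' for this model is the constant matrix \eqn{2 W^T W}.
#'
#' @param residuals numeric vector of location-model residuals.
#' @param X covariate data frame.
#' @param batch optional factor of batch labels (each level needs >= 3 rows).
#' @param max_iter,tol Fisher-scoring controls.
#' @return an object of class `scale_fit`.
#' @export
fit_logscale <- function(residuals, X, batch = NULL, max_iter = 50, tol = 1e-6) {
  validate_covariates(X)
  n <- length(residuals)
  if (n != nrow(X)) stop("length(residuals) must equal nrow(X)")
  age_center <- mean(X$age)
  age_scale <- stats::sd(X$age)
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
  d <- covar_design(X, age_center, age_scale)
  covars <- cbind(age = d$age_c, d$other)

  if (!is.null(batch)) {
    batch <- droplevels(as.factor(batch))
    if (any(table(batch) < 3)) stop("every batch needs at least 3 members to fit a scale model")
    for (lv in levels(batch)) {
      if (all(residuals[batch == lv] == 0)) {
        stop("degenerate variance: all residuals are exactly 0 in batch '", lv, "'")
      }
    }
    Bm <- batch_dummies(batch)
  } else {
    if (all(residuals == 0)) stop("degenerate variance: all residuals are exactly 0")
    Bm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }

  # overfitting guard: need n >= 10 x number of covariate slopes
  use_covars <- ncol(covars) > 0 && n >= 10 * ncol(covars)
  if (ncol(covars) > 0 && !use_covars) {
    warning("too few observations to model covariate effects on scale; fitting constant scale")
  }
  W <- if (use_covars) cbind(Bm, covars) else Bm

  # init: per-batch log ML standard deviations, zero slopes
  theta <- numeric(ncol(W))
  for (j in seq_len(ncol(Bm))) {
    idx <- Bm[, j] == 1
    theta[j] <- 0.5 * log(mean(residuals[idx]^2) + 1e-300)
  }
  ll <- function(th) {
    eta <- drop(W %*% th)
    sum(-eta - 0.5 * residuals^2 * exp(-2 * eta)) - n / 2 * log(2 * pi)
  }
  info <- 2 * crossprod(W)
  cur <- ll(theta)
  trace <- cur
  converged <- FALSE
  grad <- NULL
  for (it in seq_len(max_iter)) {
    s2 <- exp(2 * drop(W %*% theta))
    q <- residuals^2 / s2
    grad <- drop(crossprod(W, q - 1))
    step <- solve(info, grad)
    # step halving keeps the profile log-likelihood non-decreasing
    h <- 1
    repeat {
      cand <- theta + h * step
      val <- ll(cand)
      if (val >= cur - 1e-12 || h < 1e-8) break
      h <- h / 2
    }
    delta <- max(abs(h * step))
    theta <- theta + h * step
    cur <- val
    trace <- c(trace, cur)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("scale model did not converge in %d iterations; last gradient norm %.3e",
                 max_iter, sqrt(sum(grad^2))))
  }
  names(theta) <- colnames(W)

  nb <- ncol(Bm)
  if (!is.null(batch)) {
    w <- as.numeric(table(batch)[levels(batch)]) / n
    zeta <- sum(w * theta[seq_len(nb)])
    offsets <- stats::setNames(theta[seq_len(nb)] - zeta, levels(batch))
  } else {
    zeta <- theta[1]
    offsets <- NULL
  }
  eta <- if (use_covars) theta[nb + seq_len(ncol(covars))] else stats::setNames(numeric(0), character(0))
  structure(list(
    zeta = unname(zeta), coefficients = eta,
    per_batch_log_offsets = offsets,
    batch_levels = if (is.null(batch)) NULL else levels(batch),
    age_center = age_center, age_scale = age_scale,
    link = "log", loglik_trace = trace, converged = converged,
    covar_names = colnames(covars)
  ), class = "scale_fit")
}

#' Predict the (batch-free) scale from a scale fit
#'
#' @param object a `scale_fit`.
#' @param X covariate data frame.
#' @param ... unused.
#' @return strictly positive numeric vector `exp(zeta + x'eta)`.
#' @export
predict.scale_fit <- function(object, X, ...) {
  validate_covariates(X)
  d <- covar_design(X, object$age_center, object$age_scale)
  lp <- rep(object$zeta, nrow(X))
  if (length(object$coefficients)) {
    covars <- cbind(age = d$age_c, d$other)
    lp <- lp + drop(covars[, names(object$coefficients), drop = FALSE] %*% object$coefficients)
  }
  exp(lp)
}

#' Evaluate predicted location and scale at new covariates
#'
#' @param loc a `location_fit`.
#' @param scale a `scale_fit`, or a single positive number (pooled sigma).
#' @param X covariate data frame.
#' @return list with components `mean` and `scale` (strictly positive).
#' @export
predict_moments <- function(loc, scale, X) {
  mu <- predict(loc, X)
  s <- if (inherits(scale, "scale_fit")) predict(scale, X) else rep(as.numeric(scale), nrow(X))
  if (any(s <= 0)) stop("predicted scale must be strictly positive")
  list(mean = mu, scale = s)
}

#' Jointly fit location and log-linear scale by backfitting
#'
#' Alternates (a) a weighted least-squares location fit with weights
#' \eqn{1/s^2(x)} and (b) a Fisher-scoring scale fit on the current
#' residuals, until the largest coefficient change falls below `tol`.
#' The smoothing parameter is selected by GCV on the first pass and then
#' held fixed for stability.
#'
#' @inheritParams fit_location
#' @param max_outer,tol outer-loop controls.
#' @return list with elements `location`, `scale`, `iterations`.
#' @export
fit_location_scale <- function(y, X, spec = "spline", batch = NULL,
                               n_knots = 10, max_outer = 50, tol = 1e-6) {
  loc <- fit_location(y, X, spec = spec, batch = batch, n_knots = n_knots)
  lambda <- loc$lambda
  sc <- fit_logscale(loc$residuals, X, batch = batch)
  prev <- c(loc$coefficients, sc$zeta, sc$coefficients)
  iterations <- 1L
  for (it in seq(2, max_outer)) {
    s <- predict(sc, X)
    if (!is.null(batch)) {
      s <- s * exp(unname(sc$per_batch_log_offsets[as.character(batch)]))
    }
    loc <- fit_location(y, X, spec = spec, batch = batch, n_knots = n_knots,
                        weights = 1 / s^2, lambda = lambda)
    sc <- fit_logscale(loc$residuals, X, batch = batch)
    cur <- c(loc$coefficients, sc$zeta, sc$coefficients)
    iterations <- it
    if (max(abs(cur - prev)) < tol) break
    prev <- cur
  }
  list(location = loc, scale = sc, iterations = iterations)
}
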