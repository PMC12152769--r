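# Box-Cox Cole-Green (BCCG / LMS-style) normative models: growth-chart
# fits with separate linear predictors for mu (location), log sigma
# (relative scale) and nu (Box-Cox skew), plus z-score / centile scoring.
#
# Density (positivity-truncation mass omitted, standard when sigma*nu is
# small):  f(y) = y^(nu-1) exp(-z^2/2) / (mu^nu sigma sqrt(2*pi)) with
# z = ((y/mu)^nu - 1) / (nu sigma)   (nu != 0; log(y/mu)/sigma at nu = 0).

#' Describe the terms of one BCCG moment's linear predictor
#'
#' @param age one of `"none"`, `"linear"`, `"cubic"` (polynomial up to
#'   age^3) or `"spline"` (cubic B-spline basis).
#' @param sex include a linear sex term.
#' @param interaction include the age block multiplied by sex.
#' @param df basis dimension for `age = "spline"`.
#' @param batch include fixed batch effects (treatment coding) in this
#'   moment; requires a `batch` factor at fit time.
#' @return a `chart_terms` list.
#' @export
chart_terms <- function(age = c("cubic", "linear", "spline", "none"),
                        sex = TRUE, interaction = FALSE, df = 5, batch = FALSE) {
  age <- match.arg(age)
  structure(list(age = age, sex = sex, interaction = interaction,
                 df = df, batch = batch), class = "chart_terms")
}

chart_design <- function(X, terms, age_center, age_scale, batch = NULL) {
  n <- nrow(X)
  age_c <- (X$age - age_center) / age_scale
  M <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  A <- NULL
  if (terms$age == "linear") {
    A <- cbind(age = age_c)
  } else if (terms$age == "cubic") {
    A <- cbind(age = age_c, age2 = age_c^2, age3 = age_c^3)
  } else if (terms$age == "spline") {
    A <- splines::bs(age_c, df = terms$df)
    colnames(A) <- paste0("bs(age).", seq_len(ncol(A)))
  }
  if (!is.null(A)) M <- cbind(M, A)
  if (terms$sex) M <- cbind(M, sex = X$sex)
  if (terms$interaction && !is.null(A)) {
    Ai <- A * X$sex
    colnames(Ai) <- paste0(colnames(A), ":sex")
    M <- cbind(M, Ai)
  }
  if (terms$batch) {
    if (is.null(batch)) stop("terms request batch effects but no batch factor was given")
    b <- droplevels(as.factor(batch))
    if (nlevels(b) > 1) {
      Bm <- stats::model.matrix(~b)[, -1, drop = FALSE]
      colnames(Bm) <- paste0("batch:", levels(b)[-1])
      M <- cbind(M, Bm)
    }
  }
  M
}

bccg_z <- function(r, sigma, nu, logr = log(r)) {
  small <- abs(nu) < 1e-5
  z <- numeric(length(r))
  if (any(small)) z[small] <- logr[small] / sigma[small]
  if (any(!small)) {
    z[!small] <- (exp(nu[!small] * logr[!small]) - 1) / (nu[!small] * sigma[!small])
  }
  z
}

bccg_negll <- function(par, env) {
  bm <- par[env$idx_mu]; bs <- par[env$idx_sigma]; bn <- par[env$idx_nu]
  eta_mu <- drop(env$Xm %*% bm)
  mu <- if (env$mu_link == "log") exp(pmin(eta_mu, 500)) else eta_mu
  if (any(mu <= 0) || any(!is.finite(mu))) return(1e10)
  sigma <- exp(pmin(drop(env$Xs %*% bs), 50))
  nu <- drop(env$Xn %*% bn)
  logr <- env$logy - log(mu)
  z <- bccg_z(NULL, sigma, nu, logr = logr)
  ll <- sum((nu - 1) * env$logy - nu * log(mu) - log(sigma) - z^2 / 2) -
    env$n / 2 * log(2 * pi)
  if (!is.finite(ll)) return(1e10)
  -ll
}

bccg_negll_grad <- function(par, env) {
  bm <- par[env$idx_mu]; bs <- par[env$idx_sigma]; bn <- par[env$idx_nu]
  eta_mu <- drop(env$Xm %*% bm)
  mu <- if (env$mu_link == "log") exp(pmin(eta_mu, 500)) else eta_mu
  if (any(mu <= 0) || any(!is.finite(mu))) return(rep(0, length(par)))
  sigma <- exp(pmin(drop(env$Xs %*% bs), 50))
  nu <- drop(env$Xn %*% bn)
  logr <- env$logy - log(mu)
  u <- exp(nu * logr)
  z <- bccg_z(NULL, sigma, nu, logr = logr)
  dl_dlogmu <- -nu + z * u / sigma
  g_mu <- if (env$mu_link == "log") {
    drop(crossprod(env$Xm, dl_dlogmu))
  } else {
    drop(crossprod(env$Xm, dl_dlogmu / mu))
  }
  g_sigma <- drop(crossprod(env$Xs, z^2 - 1))
  small <- abs(nu) < 1e-4
  dz_dnu <- numeric(env$n)
  if (any(small)) dz_dnu[small] <- logr[small]^2 / (2 * sigma[small])
  if (any(!small)) {
    ns <- nu[!small]
    dz_dnu[!small] <- (ns * logr[!small] * u[!small] - (u[!small] - 1)) /
      (ns^2 * sigma[!small])
  }
  g_nu <- drop(crossprod(env$Xn, logr - z * dz_dnu))
  -c(g_mu, g_sigma, g_nu)
}

#' Fit a Box-Cox Cole-Green normative model
#'
#' Maximum likelihood under the BCCG density with separate linear
#' predictors for mu (identity or log link), log sigma and nu.  The primary
#' algorithm is block-coordinate backfitting across the three moments (each
#' block updated by BFGS with analytic gradients), which keeps the deviance
#' non-increasing over outer iterations; if it fails to converge, a joint
#' quasi-Newton pass over all coefficients is used as a fallback stepping
#' scheme.
#'
#' @param y strictly positive response vector.
#' @param X covariate data frame with `age` and `sex`.
#' @param mu_terms,sigma_terms,nu_terms [chart_terms()] descriptions;
#'   `nu_terms` defaults to an intercept-only (constant) skew.
#' @param mu_link `"identity"` or `"log"`.
#' @param batch optional factor for moments whose terms request batch
#'   fixed effects.
#' @param max_outer maximum outer backfitting iterations.
#' @param tol convergence tolerance on the deviance drop.
#' @return an object of class `bccg_model`.
#' @export
fit_bccg <- function(y, X,
                     mu_terms = chart_terms("cubic", sex = TRUE),
                     sigma_terms = chart_terms("cubic", sex = TRUE),
                     nu_terms = chart_terms("none", sex = FALSE),
                     mu_link = c("identity", "log"), batch = NULL,
                     max_outer = 200, tol = 1e-6) {
  mu_link <- match.arg(mu_link)
  validate_covariates(X)
  if (any(y <= 0)) stop("BCCG responses must be strictly positive")
  n <- length(y)
  age_center <- mean(X$age)
  age_scale <- stats::sd(X$age)
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1

  Xm <- chart_design(X, mu_terms, age_center, age_scale, batch)
  Xs <- chart_design(X, sigma_terms, age_center, age_scale, batch)
  Xn <- chart_design(X, nu_terms, age_center, age_scale, batch)
  p <- ncol(Xm) + ncol(Xs) + ncol(Xn)
  if (n < 10 * p) {
    stop(sprintf("n = %d is too small for %d coefficients (need n >= 10 * p)", n, p))
  }

  env <- new.env()
  env$Xm <- Xm; env$Xs <- Xs; env$Xn <- Xn
  env$logy <- log(y); env$n <- n; env$mu_link <- mu_link
  env$idx_mu <- seq_len(ncol(Xm))
  env$idx_sigma <- ncol(Xm) + seq_len(ncol(Xs))
  env$idx_nu <- ncol(Xm) + ncol(Xs) + seq_len(ncol(Xn))

  # moment-based starting values
  init_mu <- if (mu_link == "log") {
    stats::lm.fit(Xm, log(y))$coefficients
  } else {
    stats::lm.fit(Xm, y)$coefficients
  }
  init_mu[!is.finite(init_mu)] <- 0
  mu0 <- if (mu_link == "log") exp(drop(Xm %*% init_mu)) else drop(Xm %*% init_mu)
  if (any(mu0 <= 0)) { # fall back to a flat positive start
    init_mu <- c(mean(y), rep(0, ncol(Xm) - 1))
    mu0 <- rep(mean(y), n)
  }
  cv0 <- stats::sd(y / mu0 - 1)
  if (!is.finite(cv0) || cv0 <= 0) cv0 <- 0.1
  init_sigma <- c(log(cv0), rep(0, ncol(Xs) - 1))
  init_nu <- c(1, rep(0, ncol(Xn) - 1))
  par <- c(init_mu, init_sigma, init_nu)

  dev <- 2 * bccg_negll(par, env)
  dev_trace <- dev
  converged <- FALSE
  blocks <- list(env$idx_mu, env$idx_sigma, env$idx_nu)
  outer <- 0L
  for (it in seq_len(max_outer)) {
    outer <- it
    for (bl in blocks) {
      obj <- function(pb) { pp <- par; pp[bl] <- pb; bccg_negll(pp, env) }
      gr <- function(pb) { pp <- par; pp[bl] <- pb; bccg_negll_grad(pp, env)[bl] }
      opt <- tryCatch(stats::optim(par[bl], obj, gr, method = "BFGS",
                                   control = list(maxit = 100, reltol = 1e-12)),
                      error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && 2 * opt$value <= dev + 1e-12) {
        par[bl] <- opt$par
        dev <- 2 * opt$value
      }
    }
    dev_trace <- c(dev_trace, dev)
    drop_ <- dev_trace[length(dev_trace) - 1] - dev
    if (drop_ >= 0 && drop_ < tol) { converged <- TRUE; break }
  }
  algorithm <- "backfit"
  if (!converged) {
    # fallback stepping scheme: joint quasi-Newton over all coefficients
    opt <- tryCatch(stats::optim(par, bccg_negll, bccg_negll_grad, env = env,
                                 method = "BFGS",
                                 control = list(maxit = 1000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(opt)) {
      opt <- tryCatch(stats::optim(par, bccg_negll, env = env, method = "Nelder-Mead",
                                   control = list(maxit = 5000)),
                      error = function(e) NULL)
    }
    if (is.null(opt) || !is.finite(opt$value)) {
      stop(sprintf("BCCG fit failed to converge (deviance %.6g after %d outer iterations)",
                   dev, outer))
    }
    if (2 * opt$value <= dev) {
      par <- opt$par
      dev <- 2 * opt$value
    }
    dev_trace <- c(dev_trace, dev)
    algorithm <- "fallback"
    converged <- TRUE
  }

  coef_named <- function(idx, Xmat) stats::setNames(par[idx], colnames(Xmat))
  structure(list(
    mu_coef = coef_named(env$idx_mu, Xm),
    sigma_coef = coef_named(env$idx_sigma, Xs),
    nu_coef = coef_named(env$idx_nu, Xn),
    mu_terms = mu_terms, sigma_terms = sigma_terms, nu_terms = nu_terms,
    mu_link = mu_link, age_center = age_center, age_scale = age_scale,
    ref_age = mean(X$age),
    batch_levels = if (is.null(batch)) NULL else levels(droplevels(as.factor(batch))),
    deviance = dev, deviance_trace = dev_trace,
    iterations = outer, converged = converged, algorithm = algorithm,
    n = n, n_par = p,
    data = list(y = y, X = X, batch = batch)
  ), class = "bccg_model")
}

#' @export
print.bccg_model <- function(x, ...) {
  cat(sprintf("bccg_model: n=%d, %d coefficients, deviance %.4f (%s, %s)\n",
              x$n, x$n_par, x$deviance, x$algorithm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict BCCG distribution parameters at new covariates
#'
#' @param object a `bccg_model`.
#' @param X covariate data frame.
#' @param batch optional batch factor for batch-aware moments (omitted
#'   batch effects evaluate at the reference level).
#' @param ... unused.
#' @return list with vectors `mu`, `sigma`, `nu`.
#' @export
predict.bccg_model <- function(object, X, batch = NULL, ...) {
  validate_covariates(X)
  ref_batch <- function(terms) {
    if (!terms$batch) return(NULL)
    if (!is.null(batch)) return(factor(batch, levels = object$batch_levels))
    factor(rep(object$batch_levels[1], nrow(X)), levels = object$batch_levels)
  }
  dm <- chart_design(X, object$mu_terms, object$age_center, object$age_scale,
                     ref_batch(object$mu_terms))
  ds <- chart_design(X, object$sigma_terms, object$age_center, object$age_scale,
                     ref_batch(object$sigma_terms))
  dn <- chart_design(X, object$nu_terms, object$age_center, object$age_scale,
                     ref_batch(object$nu_terms))
  eta_mu <- drop(dm %*% object$mu_coef)
  list(mu = if (object$mu_link == "log") exp(eta_mu) else eta_mu,
       sigma = exp(drop(ds %*% object$sigma_coef)),
       nu = drop(dn %*% object$nu_coef))
}

#' Normative z-scores under a fitted BCCG model
#'
#' \eqn{z = ((y/\mu)^\nu - 1)/(\nu\sigma)} for \eqn{\nu \ne 0} and
#' \eqn{z = \log(y/\mu)/\sigma} at \eqn{\nu = 0}.
#'
#' @param model a `bccg_model`.
#' @param y positive observations.
#' @param X covariate data frame aligned with `y`.
#' @param batch optional batch factor (see [predict.bccg_model()]).
#' @return numeric z-score vector.
#' @export
z_score <- function(model, y, X, batch = NULL) {
  if (any(y <= 0)) stop("y must be strictly positive")
  p <- predict(model, X, batch = batch)
  bccg_z(NULL, p$sigma, p$nu, logr = log(y) - log(p$mu))
}

#' Centiles from z-scores
#'
#' @param z numeric z-scores.
#' @return `pnorm(z)`, values in (0, 1).
#' @export
centile <- function(z) stats::pnorm(z)

#' Score a cohort against a normative model
#'
#' @inheritParams z_score
#' @return list with `z` and `centile` vectors (a score set).
#' @export
score_bccg <- function(model, y, X, batch = NULL) {
  z <- z_score(model, y, X, batch = batch)
  list(z = z, centile = centile(z))
}

#' Draw BCCG variates
#'
#' Inverts the z transform: \eqn{y = \mu (1 + \nu\sigma z)^{1/\nu}} with
#' \eqn{z \sim N(0,1)} (lognormal at \eqn{\nu = 0}).  Draws whose Box-Cox
#' argument would be non-positive are redrawn (negligible mass when
#' \eqn{\sigma\nu} is small).
#'
#' @param mu,sigma,nu parameter vectors (recycled to a common length).
#' @return positive numeric vector.
#' @export
rbccg <- function(mu, sigma, nu) {
  n <- max(length(mu), length(sigma), length(nu))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  z <- stats::rnorm(n)
  for (i in 1:50) {
    bad <- abs(nu) >= 1e-5 & (1 + nu * sigma * z) <= 0
    if (!any(bad)) break
    z[bad] <- stats::rnorm(sum(bad))
  }
  ifelse(abs(nu) < 1e-5, mu * exp(sigma * z), mu * (1 + nu * sigma * z)^(1 / nu))
}

#' Standardized sex effect on predicted variance
#'
#' Predicted variance is \eqn{(\mu\sigma)^2}; the statistic is
#' \eqn{(\mathrm{Var}_M - \mathrm{Var}_F)/\mathrm{Var}_F} evaluated at
#' `ref_age`.  When the mu model carries no sex term this equals
#' \eqn{\exp(2\beta_{\sigma,sex}) - 1}.
#'
#' @param model a `bccg_model` whose sigma terms include sex.
#' @param ref_age reference age (default: the training sample's mean age).
#' @return a single standardized effect.
#' @export
sex_variance_effect <- function(model, ref_age = NULL) {
  if (!model$sigma_terms$sex) stop("sigma model has no sex term")
  if (is.null(ref_age)) ref_age <- model$ref_age
  Xr <- data.frame(age = c(ref_age, ref_age), sex = c(0, 1))
  p <- predict(model, Xr)
  v <- (p$mu * p$sigma)^2
  (v[2] - v[1]) / v[1]
}

refit_joint <- function(model) {
  fit_bccg(model$data$y, model$data$X,
           mu_terms = model$mu_terms, sigma_terms = model$sigma_terms,
           nu_terms = model$nu_terms, mu_link = model$mu_link,
           batch = model$data$batch, max_outer = 500, tol = 1e-9)
}

#' Likelihood-ratio test for a dropped sigma term
#'
#' @param full,reduced nested `bccg_model` fits (reduced drops one or more
#'   sigma coefficients).
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_sigma_term <- function(full, reduced) {
  stat <- reduced$deviance - full$deviance
  df <- full$n_par - reduced$n_par
  if (df < 1) stop("models are not nested (reduced has no fewer coefficients)")
  if (stat < -1e-6) {
    full <- refit_joint(full)
    reduced <- refit_joint(reduced)
    stat <- reduced$deviance - full$deviance
    if (stat < -1e-6) {
      stop(sprintf("reduced deviance below full deviance (%.3e) after refit; fits unreliable", stat))
    }
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
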