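# The ComBat family proper: standardization, site-effect estimation under
# the weighted sum-to-zero identifiability constraint, empirical-Bayes
# shrinkage across features, and reconstruction of harmonized observations.
#
# Methods:
#   none   - intercept-only mean model (no covariate preservation)
#   linear - linear age + sex mean model, pooled sigma
#   gam    - penalized-spline age + linear sex mean model, pooled sigma
#   ls     - penalized-spline mean model plus a log-linear scale model in
#            age and sex, so covariate effects on variance survive
#            harmonization

#' Standardize a feature against its fitted moments
#'
#' Computes \eqn{z = (y - \hat\alpha - \hat f(x)) / \hat s(x)} where the
#' denominator is the covariate-dependent scale (`scale_fit`) for the
#' location-scale method or the pooled sigma otherwise.  The batch effect is
#' deliberately left inside `z`; it is estimated there and removed during
#' reconstruction.
#'
#' @param y numeric feature vector.
#' @param loc a `location_fit`.
#' @param scale a `scale_fit` or single positive number (pooled sigma).
#' @param X covariate data frame.
#' @return numeric vector of standardized values.
#' @export
standardize <- function(y, loc, scale, X) {
  m <- predict_moments(loc, scale, X)
  if (any(m$scale < 1e-12)) stop("predicted scale below 1e-12; feature is degenerate")
  (y - m$mean) / m$scale
}

#' Invert [standardize()]
#'
#' @inheritParams standardize
#' @param z standardized values.
#' @return numeric vector on the original feature scale.
#' @export
destandardize <- function(z, loc, scale, X) {
  m <- predict_moments(loc, scale, X)
  z * m$scale + m$mean
}

#' Estimate naive (least-squares / moment) site effects
#'
#' Additive effects \eqn{\hat\gamma_{ik}} are batch means of the
#' standardized data, re-centred so that \eqn{\sum_i n_i \hat\gamma_{ik} = 0}
#' per feature.  Multiplicative effects \eqn{\hat\delta_{ik}} are ML batch
#' standard deviations of the centred standardized data; for the
#' location-scale method they are additionally renormalized so the
#' \eqn{n_i}-weighted mean of \eqn{\log\hat\delta_{ik}} is zero per feature
#' (the grand-mean deviation construction that makes the scale model
#' identifiable).
#'
#' @param z numeric matrix of standardized data, subjects x features.
#' @param batch factor of batch labels (>= 3 subjects each).
#' @param method harmonization method label (`"ls"` triggers the log-scale
#'   renormalization of delta).
#' @return an object of class `site_effects` with elements `gamma_naive`,
#'   `delta_naive` (batch x feature matrices) and `batch_sizes`.
#' @export
estimate_site_effects <- function(z, batch, method = "linear") {
  z <- as.matrix(z)
  batch <- droplevels(as.factor(batch))
  if (any(table(batch) < 3)) stop("every batch needs at least 3 subjects")
  lv <- levels(batch)
  n_i <- as.numeric(table(batch)[lv])
  w <- n_i / sum(n_i)
  K <- ncol(z)
  gamma <- matrix(NA_real_, length(lv), K, dimnames = list(lv, colnames(z)))
  delta <- gamma
  for (i in seq_along(lv)) {
    zi <- z[batch == lv[i], , drop = FALSE]
    gamma[i, ] <- colMeans(zi)
  }
  # enforce the weighted sum-to-zero constraint exactly
  gamma <- sweep(gamma, 2, colSums(gamma * w))
  for (i in seq_along(lv)) {
    zi <- z[batch == lv[i], , drop = FALSE]
    zc <- sweep(zi, 2, colMeans(zi))
    v <- colMeans(zc^2)  # ML variance about the batch mean
    if (any(v <= 0)) {
      k0 <- colnames(z)[which(v <= 0)[1]]
      stop("batch '", lv[i], "' has zero variance in feature '", k0, "'")
    }
    delta[i, ] <- sqrt(v)
  }
  if (identical(method, "ls")) {
    ld <- log(delta)
    delta <- exp(sweep(ld, 2, colSums(ld * w)))
  }
  structure(list(gamma_naive = gamma, delta_naive = delta,
                 batch_sizes = stats::setNames(n_i, lv), method = method),
            class = "site_effects")
}

# Method-of-moments inverse-gamma hyperparameters for delta^2.
ig_moments <- function(d2) {
  m <- mean(d2)
  s2 <- stats::var(d2)
  list(lambda = (m^2 + 2 * s2) / s2, theta = (m^3 + m * s2) / s2, m = m, s2 = s2)
}

#' Empirical-Bayes shrinkage of site effects
#'
#' Pools naive site effects across the features of each group using a
#' normal prior on \eqn{\gamma_{ik}} and an inverse-gamma prior on
#' \eqn{\delta^2_{ik}}, with hyperparameters estimated by the method of
#' moments across features, and solves the conditional-posterior fixed
#' point for the shrunken estimates \eqn{\gamma^*_{ik}, \delta^*_{ik}}.
#'
#' @param effects a `site_effects` object.
#' @param z standardized data matrix used to form the naive estimates.
#' @param batch factor of batch labels.
#' @param feature_groups named list partitioning feature names into
#'   shrinkage groups (default: all features in one group).
#' @param tol,max_iter fixed-point controls.
#' @return the `site_effects` object augmented with `gamma_star`,
#'   `delta_star` and per-group `hyperparameters`.
#' @export
eb_shrink <- function(effects, z, batch, feature_groups = NULL,
                      tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(effects, "site_effects"))
  z <- as.matrix(z)
  batch <- droplevels(as.factor(batch))
  lv <- rownames(effects$gamma_naive)
  feats <- colnames(effects$gamma_naive)
  if (is.null(feature_groups)) feature_groups <- list(all = feats)
  gamma_star <- effects$gamma_naive
  delta_star <- effects$delta_naive
  hyper <- list()
  for (gname in names(feature_groups)) {
    fk <- intersect(feature_groups[[gname]], feats)
    if (length(fk) < 2) {
      warning("feature group '", gname, "' has fewer than 2 features; shrinkage skipped")
      next
    }
    for (i in seq_along(lv)) {
      g_hat <- effects$gamma_naive[i, fk]
      d2_hat <- effects$delta_naive[i, fk]^2
      g_bar <- mean(g_hat)
      t2 <- stats::var(g_hat)
      n_i <- effects$batch_sizes[[lv[i]]]
      degenerate_prior <- t2 < 1e-12 && stats::var(d2_hat) < 1e-12
      if (degenerate_prior) {
        # all features agree: the prior is centred on the common value and
        # shrinkage is a no-op
        gamma_star[i, fk] <- g_hat
        delta_star[i, fk] <- sqrt(d2_hat)
        hyper[[gname]][[lv[i]]] <- list(gamma_bar = g_bar, tau2 = t2,
                                        lambda = NA_real_, theta = NA_real_,
                                        shrunk = FALSE)
        next
      }
      shrink_delta <- stats::var(d2_hat) >= 1e-12
      ig <- if (shrink_delta) ig_moments(d2_hat) else list(lambda = NA_real_, theta = NA_real_)
      if (shrink_delta && ig$lambda <= 2) {
        warning("inverse-gamma shape estimate <= 2 for batch '", lv[i],
                "', group '", gname, "'; falling back to non-EB estimates")
        hyper[[gname]][[lv[i]]] <- list(gamma_bar = g_bar, tau2 = t2,
                                        lambda = ig$lambda, theta = ig$theta,
                                        shrunk = FALSE)
        next
      }
      zi <- z[batch == lv[i], fk, drop = FALSE]
      g_star <- g_hat
      d2_star <- d2_hat
      for (it in seq_len(max_iter)) {
        g_new <- (n_i * t2 * g_hat + d2_star * g_bar) / (n_i * t2 + d2_star)
        d2_new <- if (shrink_delta) {
          ss <- colSums(sweep(zi, 2, g_new)^2)
          (ig$theta + 0.5 * ss) / (n_i / 2 + ig$lambda - 1)
        } else d2_hat
        ch <- max(abs(g_new - g_star), abs(d2_new - d2_star))
        g_star <- g_new
        d2_star <- d2_new
        if (ch < tol) break
      }
      gamma_star[i, fk] <- g_star
      delta_star[i, fk] <- sqrt(d2_star)
      hyper[[gname]][[lv[i]]] <- list(gamma_bar = g_bar, tau2 = t2,
                                      lambda = ig$lambda, theta = ig$theta,
                                      shrunk = TRUE)
    }
  }
  effects$gamma_star <- gamma_star
  effects$delta_star <- delta_star
  effects$hyperparameters <- hyper
  effects
}

#' Harmonize a feature table across batches
#'
#' The main entry point of the ComBat family.  Per feature it (1) fits the
#' method's covariate model jointly with batch intercepts, (2) standardizes
#' by the batch-free fitted mean and scale, (3) estimates additive and
#' multiplicative site effects on the standardized data, (4) optionally
#' shrinks them by empirical Bayes within feature groups, and (5)
#' reconstructs \deqn{y^* = \hat s(x)\,(z - \gamma^*)/\delta^* + \hat\alpha
#' + \hat f(x).}
#'
#' With a single batch every method acts as the identity (up to floating
#' point).  All methods are deterministic.
#'
#' @param table a [feature_table()].
#' @param method `"ls"`, `"gam"`, `"linear"` or `"none"`.
#' @param eb logical: apply empirical-Bayes shrinkage (default `TRUE`).
#' @param feature_groups named list of feature names for EB pooling;
#'   default groups by the table's category map when it is informative,
#'   otherwise a single group.
#' @param log_transform harmonize on the log scale (features must be
#'   positive); output is exponentiated back.
#' @param n_knots interior knots for spline mean models.
#' @param eb_tol fixed-point tolerance for the EB conditional posteriors.
#' @return list with `table` (harmonized `feature_table`) and `model`
#'   (a `combat_model`).
#' @export
harmonize <- function(table, method = c("ls", "gam", "linear", "none"),
                      eb = TRUE, feature_groups = NULL, log_transform = FALSE,
                      n_knots = 10, eb_tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(table, "feature_table"))
  X <- table$covariates
  batch <- droplevels(table$batch)
  if (any(table(batch) < 3)) stop("every batch needs at least 3 subjects")
  Y <- table$features
  feats <- colnames(Y)
  if (log_transform) {
    if (any(Y <= 0)) stop("log_transform requires strictly positive features")
    Y <- log(Y)
  }
  if (is.null(feature_groups)) {
    if (length(unique(table$category)) > 1) {
      feature_groups <- split(names(table$category), table$category)
    } else {
      feature_groups <- list(all = feats)
    }
  }

  mean_spec <- switch(method, none = "intercept", linear = "linear",
                      gam = "spline", ls = "spline")
  loc_fits <- vector("list", length(feats))
  scale_fits <- vector("list", length(feats))
  pooled_sigma <- stats::setNames(rep(NA_real_, length(feats)), feats)
  stand_mean <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  shat <- stand_mean
  names(loc_fits) <- names(scale_fits) <- feats

  for (k in feats) {
    y <- Y[, k]
    if (method == "ls") {
      fit <- fit_location_scale(y, X, spec = mean_spec, batch = batch,
                                n_knots = n_knots)
      loc_fits[[k]] <- fit$location
      scale_fits[[k]] <- fit$scale
      shat[, k] <- predict(fit$scale, X)
    } else {
      loc <- fit_location(y, X, spec = mean_spec, batch = batch, n_knots = n_knots)
      loc_fits[[k]] <- loc
      sig <- sqrt(mean(loc$residuals^2))
      if (sig < 1e-12) stop("feature '", k, "' has (near) zero residual variance")
      pooled_sigma[k] <- sig
      shat[, k] <- sig
    }
    stand_mean[, k] <- predict(loc_fits[[k]], X)
    if (any(shat[, k] < 1e-12)) stop("predicted scale below 1e-12 for feature '", k, "'")
  }
  z <- (Y - stand_mean) / shat

  effects <- estimate_site_effects(z, batch, method = method)
  if (eb) effects <- eb_shrink(effects, z, batch, feature_groups = feature_groups,
                               tol = eb_tol)
  g_use <- if (eb && !is.null(effects$gamma_star)) effects$gamma_star else effects$gamma_naive
  d_use <- if (eb && !is.null(effects$delta_star)) effects$delta_star else effects$delta_naive

  bi <- as.integer(batch)
  Ystar <- shat * (z - g_use[bi, , drop = FALSE]) / d_use[bi, , drop = FALSE] + stand_mean
  if (log_transform) {
    Ystar <- exp(Ystar)
  } else if (all(table$features > 0) && any(Ystar <= 0)) {
    warning("harmonized values <= 0 for a positive feature; consider log_transform = TRUE")
  }
  dimnames(Ystar) <- dimnames(table$features)

  model <- structure(list(
    method = method, eb = eb, feature_groups = feature_groups,
    log_transform = log_transform,
    location_fits = loc_fits,
    scale_fits = if (method == "ls") scale_fits else NULL,
    pooled_sigma = if (method != "ls") pooled_sigma else NULL,
    site_effects = effects,
    covariate_spec = list(mean = mean_spec,
                          scale = if (method == "ls") "log-linear in age + sex" else "pooled"),
    batch_levels = levels(batch)
  ), class = "combat_model")

  out <- table
  out$features <- Ystar
  out$provenance <- c(table$provenance, list(harmonized = method, eb = eb))
  list(table = out, model = model)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("combat_model: method=%s, eb=%s, %d feature(s), %d batch(es)\n",
              x$method, x$eb, length(x$location_fits), length(x$batch_levels)))
  invisible(x)
}

#' Serialize a harmonization model to structured text
#'
#' Writes an exact (full floating-point precision) JSON representation that
#' [read_combat_model()] restores identically.
#'
#' @param model a `combat_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  writeLines(jsonlite::serializeJSON(model, digits = I(17)), path)
  invisible(path)
}

#' Restore a harmonization model written by [write_combat_model()]
#'
#' @param path file path.
#' @return a `combat_model`.
#' @export
read_combat_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}
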