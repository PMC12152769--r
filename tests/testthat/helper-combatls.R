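# Shared fixtures and independent brute-force oracles.

make_covariates <- function(n, seed = 1, age_range = c(50, 80)) {
  set.seed(seed)
  data.frame(age = runif(n, age_range[1], age_range[2]),
             sex = rbinom(n, 1, 0.5))
}

# Independent brute-force empirical-Bayes fixed point, written as plain
# per-feature loops following the Johnson-style conditional posteriors.
# Mirrors the spec'd stopping rule (max change < tol) so trajectories are
# comparable with the package implementation.
oracle_eb <- function(gamma_hat, delta_hat, z, batch, tol = 1e-6, max_iter = 1000) {
  lv <- rownames(gamma_hat)
  feats <- colnames(gamma_hat)
  n_i <- table(batch)[lv]
  g_star <- gamma_hat
  d_star <- delta_hat
  for (i in seq_along(lv)) {
    g <- gamma_hat[i, ]
    d2 <- delta_hat[i, ]^2
    gbar <- mean(g)
    t2 <- var(g)
    m <- mean(d2)
    s2 <- var(d2)
    lam <- (m^2 + 2 * s2) / s2
    th <- (m^3 + m * s2) / s2
    ni <- as.numeric(n_i[lv[i]])
    zi <- z[batch == lv[i], , drop = FALSE]
    for (k in seq_along(feats)) {
      gs <- g[k]; d2s <- d2[k]
      for (it in 1:max_iter) {
        gs_new <- (ni * t2 * g[k] + d2s * gbar) / (ni * t2 + d2s)
        ss <- sum((zi[, k] - gs_new)^2)
        d2_new <- (th + 0.5 * ss) / (ni / 2 + lam - 1)
        ch <- max(abs(gs_new - gs), abs(d2_new - d2s))
        gs <- gs_new; d2s <- d2_new
        if (ch < tol) break
      }
      g_star[i, k] <- gs
      d_star[i, k] <- sqrt(d2s)
    }
  }
  list(gamma_star = g_star, delta_star = d_star)
}

# Independent brute-force linear ComBat (no spline, pooled sigma, EB),
# computed from first principles with explicit matrix algebra.
oracle_linear_combat <- function(Y, X, batch, eb = TRUE, tol = 1e-6) {
  batch <- droplevels(as.factor(batch))
  lv <- levels(batch)
  n <- nrow(Y)
  w <- as.numeric(table(batch)[lv]) / n
  D <- cbind(sapply(lv, function(l) as.numeric(batch == l)),
             age = (X$age - mean(X$age)) / sd(X$age), sex = X$sex)
  beta <- solve(crossprod(D), crossprod(D, Y))
  fitted <- D %*% beta
  alpha <- as.numeric(w %*% beta[seq_along(lv), , drop = FALSE])
  stand_mean <- sweep(D[, -(seq_along(lv)), drop = FALSE] %*%
                        beta[-(seq_along(lv)), , drop = FALSE], 2, -alpha)
  sigma <- sqrt(colMeans((Y - fitted)^2))
  z <- sweep(Y - stand_mean, 2, sigma, "/")
  gamma_hat <- t(sapply(lv, function(l) colMeans(z[batch == l, , drop = FALSE])))
  gamma_hat <- sweep(gamma_hat, 2, as.numeric(w %*% gamma_hat))
  delta_hat <- t(sapply(seq_along(lv), function(i) {
    zi <- z[batch == lv[i], , drop = FALSE]
    sqrt(colMeans(sweep(zi, 2, colMeans(zi))^2))
  }))
  rownames(gamma_hat) <- rownames(delta_hat) <- lv
  if (eb) {
    st <- oracle_eb(gamma_hat, delta_hat, z, batch, tol = tol)
    g_use <- st$gamma_star; d_use <- st$delta_star
  } else {
    g_use <- gamma_hat; d_use <- delta_hat
  }
  bi <- as.integer(batch)
  ystar <- sweep((z - g_use[bi, , drop = FALSE]) / d_use[bi, , drop = FALSE],
                 2, sigma, "*") + stand_mean
  list(harmonized = ystar, gamma_hat = gamma_hat, delta_hat = delta_hat,
       gamma_star = g_use, delta_star = d_use, z = z, sigma = sigma)
}

# A small multi-feature table with injected batch effects, for
# harmonization tests.
make_batch_table <- function(n = 120, n_feat = 8, n_batch = 3, seed = 42,
                             gamma_sd = 0.5, delta_sd = 0.3) {
  set.seed(seed)
  X <- data.frame(age = runif(n, 50, 80), sex = rbinom(n, 1, 0.5))
  batch <- factor(sample(LETTERS[seq_len(n_batch)], n, TRUE))
  gam <- matrix(rnorm(n_batch * n_feat, 0, gamma_sd), n_batch)
  del <- matrix(exp(rnorm(n_batch * n_feat, 0, delta_sd)), n_batch)
  Y <- sapply(seq_len(n_feat), function(k) {
    mu <- 50 + 10 * k + 2 * X$sex - 0.1 * X$age
    bi <- as.integer(batch)
    mu + gam[bi, k] + del[bi, k] * rnorm(n)
  })
  colnames(Y) <- paste0("f", seq_len(n_feat))
  list(table = feature_table(Y, X, batch), gamma = gam, delta = del,
       X = X, batch = batch, Y = Y)
}
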