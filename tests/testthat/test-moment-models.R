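test_that("constant and exact-linear responses are recovered exactly", {
  X <- make_covariates(200, seed = 1)
  for (spec in c("linear", "spline")) {
    fit <- fit_location(rep(7, 200), X, spec = spec)
    expect_equal(fit$intercept, 7, tolerance = 1e-10)
    expect_lt(max(abs(fit$coefficients[-1])), 1e-8)
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
  age_c <- (X$age - mean(X$age)) / sd(X$age)
  y <- 2 + 3 * age_c + 1 * X$sex
  fit <- fit_location(y, X, spec = "linear")
  # normal-equations oracle
  D <- cbind(1, X$sex, age_c)
  beta <- solve(crossprod(D), crossprod(D, y))
  expect_equal(unname(fit$coefficients), unname(drop(beta)), tolerance = 1e-8)
  expect_equal(unname(predict(fit, data.frame(age = mean(X$age) + sd(X$age), sex = 1))),
               6, tolerance = 1e-8)
})

test_that("penalized spline contains the linear null space and tracks mgcv", {
  X <- make_covariates(400, seed = 2)
  y_line <- 1 + 0.5 * X$age
  fit <- fit_location(y_line, X, spec = "spline")
  expect_lt(max(abs(fit$fitted - y_line)), 1e-6)

  skip_if_not_installed("mgcv")
  set.seed(3)
  y <- sin(X$age / 5) + 0.02 * X$age + 0.3 * X$sex + rnorm(400, 0, 0.1)
  fit <- fit_location(y, X, spec = "spline")
  g <- mgcv::gam(y ~ s(age, bs = "ps") + sex, data = X)
  expect_lt(sqrt(mean((fit$fitted - fitted(g))^2)), 0.05 * sd(y))
})

test_that("log-scale ML fit recovers planted effects and matches a gamma-GLM oracle", {
  n <- 2e4
  X <- make_covariates(n, seed = 4)
  set.seed(5)
  r <- exp(0.5 + 0.3 * X$sex) * rnorm(n)
  fit <- fit_logscale(r, X)
  # independent oracle: ML of the log-variance model is a gamma GLM on r^2
  # with log link; its coefficients are twice the log-sd coefficients
  age_c <- (X$age - mean(X$age)) / sd(X$age)
  g <- glm(r^2 ~ age_c + X$sex, family = Gamma(link = "log"))
  expect_equal(unname(fit$zeta), unname(coef(g)[1] / 2), tolerance = 1e-5)
  expect_equal(unname(fit$coefficients[["sex"]]), unname(coef(g)[3] / 2),
               tolerance = 1e-5)
  expect_equal(unname(fit$coefficients[["sex"]]), 0.3, tolerance = 0.05)
  # null effect
  set.seed(6)
  fit0 <- fit_logscale(rnorm(n), X)
  expect_lt(abs(fit0$coefficients[["sex"]]), 0.05)
  # profile log-likelihood is non-decreasing and predictions positive
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_true(all(predict(fit, X) > 0))
})

test_that("batch-aware scale fits report constrained per-batch offsets", {
  n <- 5000
  X <- make_covariates(n, seed = 7)
  set.seed(8)
  b <- factor(sample(c("A", "B", "C"), n, TRUE, prob = c(0.5, 0.3, 0.2)))
  off <- c(A = 0.3, B = -0.2, C = 0.1)
  r <- exp(0.2 + 0.25 * X$sex + off[b]) * rnorm(n)
  fit <- fit_logscale(r, X, batch = b)
  w <- as.numeric(table(b)) / n
  expect_lt(abs(sum(w * fit$per_batch_log_offsets)), 1e-8)
  # offsets recovered up to their common mean
  expect_equal(unname(fit$per_batch_log_offsets),
               unname(off - sum(w * off)), tolerance = 0.05)
  expect_error(fit_logscale(r[1:5], X[1:5, ], batch = factor(c(1, 1, 2, 2, 2))),
               "at least 3")
  expect_error(fit_logscale(rep(0, 100), make_covariates(100)), "degenerate")
  expect_warning(fit_logscale(rnorm(15), make_covariates(15, seed = 9)),
                 "too few")
})

test_that("predict_moments is deterministic and extrapolates linearly with a warning", {
  X <- make_covariates(300, seed = 10)
  set.seed(11)
  y <- 10 + 0.2 * X$age + rnorm(300)
  loc <- fit_location(y, X, spec = "spline")
  sc <- fit_logscale(loc$residuals, X)
  m <- predict_moments(loc, sc, X)
  expect_equal(m$mean, loc$fitted, tolerance = 1e-10)
  expect_true(all(m$scale > 0))
  # zero-coefficient scale model predicts exactly exp(zeta)
  sc0 <- sc; sc0$coefficients[] <- 0; sc0$zeta <- 0
  expect_equal(predict(sc0, X), rep(1, 300))
  # beyond the training range: warning + linear extension
  Xout <- data.frame(age = max(X$age) + c(1, 2), sex = c(0, 0))
  expect_warning(p_out <- predict(loc, Xout), "extrapolation")
  expect_equal(diff(p_out) / 1,
               suppressWarnings(diff(predict(loc, data.frame(age = max(X$age) + c(5, 6), sex = 0)))),
               tolerance = 1e-8)
})

test_that("the scale model sees residuals only through their magnitudes", {
  X <- make_covariates(2000, seed = 30)
  set.seed(31)
  r <- exp(0.1 + 0.2 * X$sex) * rnorm(2000)
  f1 <- fit_logscale(r, X)
  f2 <- fit_logscale(-r, X)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$zeta, f2$zeta, tolerance = 1e-10)
})

test_that("degenerate designs raise informative errors", {
  X <- make_covariates(100, seed = 12)
  X$dup <- X$sex  # collinear with sex
  expect_error(fit_location(rnorm(100), X, spec = "linear"), "collinear")
  expect_error(fit_location(rnorm(20), make_covariates(20, seed = 13),
                            spec = "spline", n_knots = 20), "knots")
})

test_that("refitting on fitted values plus residuals reproduces coefficients", {
  X <- make_covariates(500, seed = 14)
  set.seed(15)
  y <- 5 + 0.1 * X$age + X$sex + rnorm(500, 0, 0.5)
  fit <- fit_location(y, X, spec = "spline")
  fit2 <- fit_location(fit$fitted + fit$residuals, X, spec = "spline",
                       lambda = fit$lambda)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-8)
})

test_that("location-scale backfit converges and respects the scale structure", {
  n <- 4000
  X <- make_covariates(n, seed = 16)
  set.seed(17)
  y <- 100 + 0.5 * X$age + 4 * X$sex + exp(0.4 + 0.3 * X$sex) * rnorm(n)
  fit <- fit_location_scale(y, X, spec = "spline")
  expect_lt(fit$iterations, 50)
  # sampling sd of eta_sex at n = 4000 is about 0.022
  expect_lt(abs(fit$scale$coefficients[["sex"]] - 0.3), 0.08)
})
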