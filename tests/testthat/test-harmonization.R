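test_that("standardization matches hand computation and inverts algebraically", {
  X <- data.frame(age = c(60, 65, 70), sex = c(0, 0, 0))
  y <- c(1, 2, 3)
  loc <- fit_location(y, X, spec = "intercept")
  sigma <- sqrt(mean(loc$residuals^2))  # ML divisor n
  z <- standardize(y, loc, sigma, X)
  expect_equal(z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # algebraic round trip on random data
  set.seed(1)
  X2 <- make_covariates(100, seed = 1)
  y2 <- rnorm(100, 50, 5)
  loc2 <- fit_location(y2, X2, spec = "linear")
  sc2 <- fit_logscale(loc2$residuals, X2)
  zz <- standardize(y2, loc2, sc2, X2)
  expect_equal(destandardize(zz, loc2, sc2, X2), y2, tolerance = 1e-10)
  expect_lt(abs(mean(standardize(y2, loc2, sqrt(mean(loc2$residuals^2)), X2))), 1e-8)
})

test_that("naive site effects honor the identifiability constraints", {
  # single batch: constraint and normalization force gamma = 0, delta = 1
  z1 <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  z1 <- scale(z1, scale = FALSE)
  z1 <- sweep(z1, 2, sqrt(colMeans(z1^2)), "/")
  se1 <- estimate_site_effects(z1, rep("A", 30), method = "ls")
  expect_equal(unname(se1$gamma_naive[1, ]), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(se1$delta_naive[1, ]), c(1, 1), tolerance = 1e-6)

  # two equal batches shifted +-0.5: weighted-mean oracle
  set.seed(2)
  b <- rep(c("A", "B"), each = 50)
  z2 <- matrix(rnorm(100, 0, 0.2), 100, 1, dimnames = list(NULL, "f"))
  z2 <- z2 - mean(z2) + ifelse(b == "A", 0.5, -0.5)
  se2 <- estimate_site_effects(z2, b)
  expect_equal(unname(se2$gamma_naive[, 1]),
               c(mean(z2[b == "A"]), mean(z2[b == "B"])) - mean(z2),
               tolerance = 1e-10)
  expect_lt(abs(se2$gamma_naive["A", 1] - 0.5), 0.1)
  expect_lt(abs(sum(se2$batch_sizes * se2$gamma_naive[, 1])), 1e-8)

  # ls renormalization: weighted mean of log delta is zero per feature
  set.seed(3)
  b3 <- rep(c("A", "B", "C"), times = c(40, 30, 50))
  z3 <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("f", 1:4)))
  z3[b3 == "B", ] <- z3[b3 == "B", ] * 2
  se3 <- estimate_site_effects(z3, b3, method = "ls")
  w <- se3$batch_sizes / sum(se3$batch_sizes)
  expect_lt(max(abs(colSums(log(se3$delta_naive) * w))), 1e-8)

  zbad <- z3; zbad[b3 == "A", 2] <- 1
  expect_error(estimate_site_effects(zbad, b3), "zero variance")
})

test_that("EB shrinkage matches a brute-force fixed point and is a contraction", {
  bt <- make_batch_table(n = 120, n_feat = 8, n_batch = 3, seed = 42)
  h <- harmonize(bt$table, method = "linear", eb = TRUE, eb_tol = 1e-12,
                 feature_groups = list(all = colnames(bt$Y)))
  eff <- h$model$site_effects
  o <- oracle_linear_combat(bt$Y, bt$X, bt$batch, eb = TRUE, tol = 1e-12)
  expect_lt(max(abs(eff$gamma_star - o$gamma_star)), 1e-8)
  expect_lt(max(abs(eff$delta_star - o$delta_star)), 1e-8)
  # gamma* lies between gamma_hat and the prior mean
  for (i in seq_len(nrow(eff$gamma_naive))) {
    gbar <- mean(eff$gamma_naive[i, ])
    expect_true(all(abs(eff$gamma_star[i, ] - gbar) <=
                      abs(eff$gamma_naive[i, ] - gbar) + 1e-12))
  }
})

test_that("a degenerate prior makes EB a no-op and shrinkage vanishes with batch size", {
  # identical naive effects across features -> prior centred on them
  z <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  b <- rep(c("A", "B"), each = 50)
  z[b == "B", ] <- z[b == "B", ] + 1
  zc <- z
  zc[, 2] <- zc[, 1]; zc[, 3] <- zc[, 1]
  eff <- estimate_site_effects(zc, b)
  shr <- eb_shrink(eff, zc, b)
  expect_equal(shr$gamma_star, shr$gamma_naive, tolerance = 1e-6)
  expect_equal(shr$delta_star, shr$delta_naive, tolerance = 1e-6)

  # shrinkage -> 0 as batches grow
  gap <- sapply(c(10, 1000), function(ni) {
    bt <- make_batch_table(n = 3 * ni, n_feat = 6, n_batch = 3, seed = ni)
    h <- harmonize(bt$table, method = "linear",
                   feature_groups = list(all = paste0("f", 1:6)))
    eff <- h$model$site_effects
    max(abs(eff$gamma_star - eff$gamma_naive))
  })
  expect_gt(gap[1] / gap[2], 5)
})

test_that("single-batch harmonization is the identity for every method", {
  n <- 200
  X <- make_covariates(n, seed = 5)
  set.seed(6)
  Y <- cbind(f1 = 100 + 5 * X$sex + rnorm(n, 0, 3),
             f2 = 50 + 0.5 * X$age + exp(0.2 * X$sex) * rnorm(n))
  ft <- feature_table(Y, X, batch = rep("A", n))
  for (m in c("none", "linear", "gam", "ls")) {
    h <- harmonize(ft, method = m)
    expect_lt(max(abs(h$table$features - Y)), 1e-8)
  }
})

test_that("row order invariance and input validation", {
  bt <- make_batch_table(n = 90, n_feat = 3, seed = 7)
  h1 <- harmonize(bt$table, method = "linear")
  perm <- sample(90)
  ftp <- feature_table(bt$Y[perm, ], bt$X[perm, ], bt$batch[perm],
                       subject_id = bt$table$subject_id[perm])
  h2 <- harmonize(ftp, method = "linear")
  expect_equal(h2$table$features, h1$table$features[perm, ], tolerance = 1e-9)
  expect_error(harmonize(bt$table, method = "bogus"))
  expect_error(feature_table(bt$Y, bt$X[, "age", drop = FALSE], bt$batch),
               "'age' and 'sex'")
})

test_that("linear ComBat matches an independent implementation", {
  bt <- make_batch_table(n = 150, n_feat = 5, n_batch = 3, seed = 8)
  h <- harmonize(bt$table, method = "linear", eb = TRUE, eb_tol = 1e-12,
                 feature_groups = list(all = paste0("f", 1:5)))
  o <- oracle_linear_combat(bt$Y, bt$X, bt$batch, eb = TRUE, tol = 1e-12)
  expect_lt(max(abs(h$table$features - o$harmonized)), 1e-8)

  skip_if_not_installed("sva")
  mod <- stats::model.matrix(~ scale(bt$X$age) + bt$X$sex)
  sv <- t(suppressMessages(sva::ComBat(dat = t(bt$Y), batch = bt$batch, mod = mod)))
  # conventions differ slightly (variance divisors); agreement is approximate
  expect_lt(max(abs(h$table$features - sv)), 0.05 * stats::median(apply(bt$Y, 2, sd)))
})

test_that("injected additive batch shifts are removed", {
  n <- 600
  X <- make_covariates(n, seed = 9)
  set.seed(10)
  b <- factor(rep(c("A", "B"), each = n / 2))
  y <- 10 + 2 * X$sex + rnorm(n) + ifelse(b == "B", 2, 0)
  ft <- feature_table(cbind(f1 = y, f2 = y + rnorm(n, 0, 0.5)), X, batch = b)
  h <- harmonize(ft, method = "linear")
  res <- resid(lm(h$table$features[, 1] ~ X$sex + X$age))
  expect_lt(abs(mean(res[b == "A"]) - mean(res[b == "B"])), 0.05)
})

test_that("ls preserves a sex-dependent variance ratio that gam attenuates", {
  set.seed(11)
  n <- 10000
  X <- data.frame(age = runif(n, 50, 80), sex = rep(c(1, 0), each = n / 2))
  b <- character(n)
  m <- which(X$sex == 1); f <- which(X$sex == 0)
  b[m] <- sample(rep(c("S1", "S2"), c(4000, 1000)))
  b[f] <- sample(rep(c("S1", "S2"), c(1000, 4000)))
  mk <- function() 100 + 3 * X$sex + exp(0.3 + 0.25 * X$sex) * rnorm(n)
  ft <- feature_table(cbind(f1 = mk(), f2 = mk()), X, batch = b)
  truth <- exp(0.5)
  ratio <- function(yh) {
    res <- resid(lm(yh ~ X$sex + poly(X$age, 2)))
    var(res[X$sex == 1]) / var(res[X$sex == 0])
  }
  r_ls <- ratio(harmonize(ft, method = "ls")$table$features[, 1])
  r_gam <- ratio(harmonize(ft, method = "gam")$table$features[, 1])
  expect_lt(abs(r_ls - truth) / truth, 0.1)
  expect_lt(abs(r_gam - 1), abs(truth - 1))  # attenuated toward 1
  expect_lt(abs(r_ls - truth), abs(r_gam - truth))
})

test_that("model serialization round-trips exactly and log_transform keeps positivity", {
  bt <- make_batch_table(n = 90, n_feat = 3, seed = 12)
  h <- harmonize(bt$table, method = "ls")
  path <- tempfile(fileext = ".json")
  write_combat_model(h$model, path)
  expect_identical(read_combat_model(path), h$model)

  Ypos <- abs(bt$Y) + 10
  ftp <- feature_table(Ypos, bt$X, bt$batch)
  hl <- harmonize(ftp, method = "linear", log_transform = TRUE)
  expect_true(all(hl$table$features > 0))
  expect_error(harmonize(feature_table(bt$Y - max(bt$Y), bt$X, bt$batch),
                         method = "linear", log_transform = TRUE), "positive")
})
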