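test_that("centile errors follow the inflation sign convention", {
  A <- matrix(c(0.80, 0.5), 1)
  B <- matrix(c(0.75, 0.5), 1)
  expect_equal(centile_error(A, B), matrix(c(0.05, 0), 1))
  expect_equal(centile_error(B, B), matrix(c(0, 0), 1))
  expect_error(centile_error(matrix(1, 2, 2), matrix(1, 3, 2)), "aligned")
})

test_that("rank-Welch test matches hand computation and is transform-invariant", {
  # {1,2,3} vs {10,11,12}: ranks {1,2,3} vs {4,5,6}
  r <- rank_welch_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-8)
  # invariance under strictly monotone transforms of the pooled inputs
  r2 <- rank_welch_test(exp(c(1, 2, 3) / 3), exp(c(10, 11, 12) / 3))
  expect_equal(r2$statistic, r$statistic)
  expect_equal(r2$p, r$p)
  # antisymmetry under swapping the two methods
  rs <- rank_welch_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(rs$statistic, -r$statistic)
  # paired identical -> degenerate
  r3 <- rank_welch_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
  # paired version is a one-sample t on rank differences
  set.seed(1)
  a <- rnorm(30); b <- a + rnorm(30, 0.5)
  rp <- rank_welch_test(a, b, paired = TRUE)
  rr <- rank(c(a, b))
  tt <- t.test(rr[1:30] - rr[31:60])
  expect_equal(rp$statistic, unname(tt$statistic))
  expect_equal(rp$p, tt$p.value)
})

test_that("rank-Welch type-I error is calibrated", {
  set.seed(2)
  rej <- mean(replicate(1000, rank_welch_test(rnorm(50), rnorm(50))$p < 0.05))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("sex-difference metric is the difference of medians and antisymmetric", {
  err <- cbind(f = c(0.2, 0.2, 0.1, 0.1))
  sex <- c(1, 1, 0, 0)
  expect_equal(unname(sex_difference_metric(err, sex)), 0.1)
  expect_equal(unname(sex_difference_metric(err, 1 - sex)), -0.1)
})

test_that("bias over replications is a calibrated one-sample t-test", {
  set.seed(3)
  strong <- rnorm(100, 0.1, 0.01)
  expect_lt(bias_over_replications(strong)$p, 1e-10)
  expect_warning(res0 <- bias_over_replications(rep(0, 10)), "constant")
  expect_equal(res0$p, 1)
  set.seed(4)
  rej <- mean(replicate(500, bias_over_replications(rnorm(100))$p < 0.05))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("extreme-centile proportions count females in the tails", {
  mc <- c(0.10, 0.15, 0.85, 0.90)
  sex <- c(0, 0, 0, 1)
  res <- extreme_centile_proportions(mc, sex)
  expect_equal(res$prop_female_low, 1)
  expect_equal(res$prop_female_high, 0.5)
  # identical scores -> zero bias
  res2 <- extreme_centile_proportions(mc, sex, expected = res)
  expect_equal(res2$low_bias, 0)
  expect_equal(res2$high_bias, 0)
  expect_warning(res3 <- extreme_centile_proportions(c(0.5, 0.6, 0.9), c(0, 1, 0)),
                 "low extreme")
  expect_true(is.na(res3$prop_female_low))
})

test_that("FDR correction is the Benjamini-Hochberg step-up", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(50)
  q <- fdr_correct(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("site-effect sizes vanish without batch effects and track injected shifts", {
  panel <- feature_panel(paste0("f", 1:4), "other", mu0 = 100 + 10 * (1:4),
                         zeta = log(4), eta_sex = 0.1, nu = NA)
  spec <- simulation_spec(n_subjects = 2000, panel = panel, seed = 10)
  sc <- generate_features(generate_cohort(spec), spec)
  f2_null <- site_effect_size(sc$table)
  expect_lt(median(f2_null$f2, na.rm = TRUE), 0.005)

  # additive shift of 1 residual SD across 2 equal batches: analytic f2 = 1/4
  set.seed(11)
  n <- 4000
  X <- make_covariates(n, seed = 11)
  b <- rep(c("A", "B"), each = n / 2)
  y <- 100 + 4 * (b == "B") + 4 * rnorm(n)
  ft <- feature_table(cbind(f = y), X, batch = b)
  f2 <- site_effect_size(ft, mu_terms = chart_terms("none", sex = FALSE),
                         sigma_terms = chart_terms("none", sex = FALSE))$f2
  expect_lt(abs(f2 - 0.25) / 0.25, 0.15)

  # monotone in the injected shift
  f2s <- sapply(c(0, 1, 2, 4, 8), function(d) {
    yk <- 100 + d * (b == "B") + 4 * rnorm(n)
    site_effect_size(feature_table(cbind(f = yk), X, batch = b),
                     mu_terms = chart_terms("none", sex = FALSE),
                     sigma_terms = chart_terms("none", sex = FALSE))$f2
  })
  expect_true(all(diff(f2s) > -0.005))
})

test_that("centile divergence summarizes per-subject differences and extremes", {
  A <- rbind(c(0.50, 0.96))
  B <- rbind(c(0.60, 0.90))
  d <- centile_divergence(A, B, extreme = 0.05)
  expect_equal(d$mean_abs_diff, 0.08)
  expect_equal(d$discrepant_extremes, 1)
  d0 <- centile_divergence(A, A)
  expect_equal(d0$mean_abs_diff, 0)
  expect_equal(d0$discrepant_extremes, 0)

  # planted age-deviation effect is recovered with a positive slope
  set.seed(6)
  n <- 500
  age <- runif(n, 40, 80)
  batch <- rep(c("A", "B"), each = n / 2)
  bm <- tapply(age, batch, mean)[batch]
  dev <- abs(age - as.numeric(bm))
  base <- matrix(runif(n * 4, 0.3, 0.7), n)
  diffm <- matrix(0.002 * dev + rnorm(n * 4, 0, 0.005), n)
  dd <- centile_divergence(base, base + diffm, age = age, batch = batch)
  expect_gt(coef(dd$regression)[["age_dev"]], 0)
})
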