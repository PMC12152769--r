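# Evaluation statistics: centile errors, rank-based Welch tests,
# sex-difference and sex-bias summaries, extreme-centile proportions,
# FDR correction, residual site-effect sizes and method-divergence
# summaries.

#' Centile errors: harmonized minus ground truth
#'
#' Positive values indicate harmonization-induced centile inflation.
#'
#' @param harmonized,true matrices (or vectors) of centiles on (0, 1),
#'   aligned subject x feature.
#' @return matrix/vector of elementwise differences.
#' @export
centile_error <- function(harmonized, true) {
  if (!identical(dim(harmonized), dim(true)) ||
      !identical(length(harmonized), length(true))) {
    stop("harmonized and true score sets are not aligned")
  }
  err <- harmonized - true
  if (anyNA(err)) stop("centile errors contain missing values")
  err
}

#' Two-tailed t-test with Welch's correction on ranks
#'
#' Pools both samples, converts to mid-ranks (average ties), then runs
#' either a Welch two-sample t-test (unpaired) or a one-sample t-test on
#' within-pair rank differences (paired).  Rank transformation makes the
#' test invariant to any strictly monotone transform of the inputs.
#'
#' @param a,b numeric vectors (equal length when `paired`).
#' @param paired logical.
#' @return list with `statistic`, `df`, `p`.
#' @export
rank_welch_test <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b)) stop("paired test needs equal lengths")
  if (length(a) < 3 || length(b) < 3) stop("need at least 3 values per group")
  r <- rank(c(a, b))
  ra <- r[seq_along(a)]
  rb <- r[length(a) + seq_along(b)]
  degenerate <- function() {
    warning("all values identical; degenerate rank test")
    list(statistic = 0, df = NA_real_, p = 1)
  }
  if (paired) {
    d <- ra - rb
    if (stats::sd(d) == 0) {
      if (all(d == 0)) return(list(statistic = 0, df = length(d) - 1, p = 1))
      return(degenerate())
    }
    tt <- stats::t.test(d)
  } else {
    if (stats::sd(ra) == 0 && stats::sd(rb) == 0) return(degenerate())
    tt <- stats::t.test(ra, rb, var.equal = FALSE)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Per-feature sex difference in median centile error
#'
#' Median male error minus median female error; negative values mean
#' males' centiles are underestimated relative to females'.
#'
#' @param errors subject x feature matrix of centile errors.
#' @param sex 0/1 vector (0 = female).
#' @return named numeric vector, one value per feature.
#' @export
sex_difference_metric <- function(errors, sex) {
  errors <- as.matrix(errors)
  stopifnot(nrow(errors) == length(sex), all(sex %in% 0:1))
  apply(errors, 2, function(e) {
    stats::median(e[sex == 1]) - stats::median(e[sex == 0])
  })
}

#' One-sample t-test of per-replicate summaries against zero
#'
#' @param x numeric vector (e.g., per-replicate category medians of the
#'   sex-difference metric).
#' @return list with `statistic`, `df`, `p`, `mean`, `conf_int` (95%).
#' @export
bias_over_replications <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 replicates")
  if (stats::sd(x) == 0) {
    warning("replicate summaries are constant; degenerate one-sample test")
    return(list(statistic = if (x[1] == 0) 0 else Inf * sign(x[1]),
                df = length(x) - 1, p = if (x[1] == 0) 1 else 0,
                mean = x[1], conf_int = c(x[1], x[1])))
  }
  tt <- stats::t.test(x, mu = 0)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = unname(tt$estimate),
       conf_int = unname(tt$conf.int))
}

#' Proportion of females among extreme mean centiles
#'
#' @param mean_centiles per-subject average centile (one feature category).
#' @param sex 0/1 vector (0 = female).
#' @param low,high extreme cuts (defaults 0.20 / 0.80).
#' @param expected optional list with `prop_female_low` / `prop_female_high`
#'   computed from true scores; when given, biases (observed - expected)
#'   are included.
#' @return list with `prop_female_low`, `prop_female_high`, counts, and
#'   (optionally) `low_bias`, `high_bias`.  Empty groups yield `NA` with a
#'   warning.
#' @export
extreme_centile_proportions <- function(mean_centiles, sex, low = 0.2, high = 0.8,
                                        expected = NULL) {
  stopifnot(low > 0, high < 1, low < high, length(mean_centiles) == length(sex))
  lo_idx <- which(mean_centiles < low)
  hi_idx <- which(mean_centiles > high)
  prop <- function(idx, lab) {
    if (!length(idx)) {
      warning("no subjects in the ", lab, " extreme group; proportion undefined")
      return(NA_real_)
    }
    mean(sex[idx] == 0)
  }
  out <- list(prop_female_low = prop(lo_idx, "low"),
              prop_female_high = prop(hi_idx, "high"),
              n_low = length(lo_idx), n_high = length(hi_idx))
  if (!is.null(expected)) {
    out$low_bias <- out$prop_female_low - expected$prop_female_low
    out$high_bias <- out$prop_female_high - expected$prop_female_high
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p numeric vector of p-values.
#' @return q-values (monotone step-up adjustment).
#' @export
fdr_correct <- function(p) stats::p.adjust(p, method = "BH")

#' Residual site-effect size (Cohen's f-squared) per feature
#'
#' Refits the normative model with and without fixed batch effects in the
#' mu and sigma moments and converts the likelihood gain into a local
#' effect size via the generalized pseudo-R-squared
#' \eqn{R^2 = 1 - \exp(-(2/n)(\ell - \ell_{null}))} (null = intercept-only
#' model), then \eqn{f^2 = (R^2_{full} - R^2_{reduced}) /
#' (1 - R^2_{full})}.
#'
#' @param table a [feature_table()] with >= 2 batches.
#' @param mu_terms,sigma_terms,nu_terms chart terms for the reduced model;
#'   the full model adds batch effects to mu and sigma.
#' @param mu_link link for mu.
#' @param normalized use the Cragg-Uhler normalization (divide by the
#'   maximum attainable R-squared); default `FALSE`.
#' @return data frame with one row per feature: `f2`, `r2_full`,
#'   `r2_reduced`, `converged`.
#' @export
site_effect_size <- function(table,
                             mu_terms = chart_terms("cubic", sex = TRUE),
                             sigma_terms = chart_terms("cubic", sex = TRUE),
                             nu_terms = chart_terms("none", sex = FALSE),
                             mu_link = "identity", normalized = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (nlevels(table$batch) < 2) stop("need at least 2 batches")
  X <- table$covariates
  batch <- table$batch
  n <- nrow(X)
  with_batch <- function(tm) { tm$batch <- TRUE; tm }
  rows <- lapply(colnames(table$features), function(k) {
    y <- table$features[, k]
    fits <- tryCatch({
      null <- fit_bccg(y, X, mu_terms = chart_terms("none", sex = FALSE),
                       sigma_terms = chart_terms("none", sex = FALSE),
                       nu_terms = chart_terms("none", sex = FALSE),
                       mu_link = mu_link)
      red <- fit_bccg(y, X, mu_terms = mu_terms, sigma_terms = sigma_terms,
                      nu_terms = nu_terms, mu_link = mu_link)
      full <- fit_bccg(y, X, mu_terms = with_batch(mu_terms),
                       sigma_terms = with_batch(sigma_terms),
                       nu_terms = nu_terms, mu_link = mu_link, batch = batch)
      list(null = null, red = red, full = full)
    }, error = function(e) NULL)
    if (is.null(fits)) {
      warning("normative fits failed for feature '", k, "'; excluded")
      return(data.frame(feature = k, f2 = NA_real_, r2_full = NA_real_,
                        r2_reduced = NA_real_, converged = FALSE))
    }
    r2 <- function(m) {
      val <- 1 - exp((m$deviance - fits$null$deviance) / n)
      if (normalized) val <- val / (1 - exp(-fits$null$deviance / n))
      val
    }
    r2f <- r2(fits$full); r2r <- r2(fits$red)
    f2 <- (r2f - r2r) / (1 - r2f)
    if (f2 < -1e-6) stop("negative f-squared beyond tolerance for feature '", k, "'")
    data.frame(feature = k, f2 = max(f2, 0), r2_full = r2f, r2_reduced = r2r,
               converged = fits$full$converged && fits$red$converged)
  })
  do.call(rbind, rows)
}

#' Divergence between two methods' centile scores
#'
#' Per subject: the mean absolute centile difference across features, and
#' the count of features where exactly one method places the subject
#' beyond the extreme tails.  Optionally regresses the mean absolute
#' difference on batch mean age, batch age range and the subject's
#' absolute deviation from the batch mean age, controlling for batch size.
#'
#' @param scores_a,scores_b subject x feature centile matrices.
#' @param extreme tail probability defining "extreme" centiles (default
#'   0.05: below 5% or above 95%).
#' @param age,batch optional vectors enabling the companion regression.
#' @return list with `mean_abs_diff`, `discrepant_extremes` (per subject)
#'   and, when age/batch are given, `regression` (lm fit).
#' @export
centile_divergence <- function(scores_a, scores_b, extreme = 0.05,
                               age = NULL, batch = NULL) {
  A <- as.matrix(scores_a); B <- as.matrix(scores_b)
  stopifnot(identical(dim(A), dim(B)), extreme > 0, extreme < 0.5)
  mad_ <- rowMeans(abs(A - B))
  ext <- function(M) M < extreme | M > 1 - extreme
  disc <- rowSums(xor(ext(A), ext(B)))
  out <- list(mean_abs_diff = mad_, discrepant_extremes = disc)
  if (!is.null(age) && !is.null(batch)) {
    batch <- as.factor(batch)
    bm <- tapply(age, batch, mean)[batch]
    br <- tapply(age, batch, function(a) diff(range(a)))[batch]
    bn <- tapply(age, batch, length)[batch]
    df <- data.frame(mad = mad_, batch_mean_age = as.numeric(bm),
                     batch_age_range = as.numeric(br),
                     age_dev = abs(age - as.numeric(bm)),
                     batch_size = as.numeric(bn))
    out$regression <- stats::lm(
      mad ~ batch_mean_age + batch_age_range + age_dev + batch_size, data = df)
  }
  out
}
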