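# Synthetic-cohort generator and experiment driver: UK-Biobank-style
# feature panels with sex/age effects on mean and log-scale, weighted
# sex-imbalanced site assignment, optional injected batch effects, and the
# resample-sites replication protocol.

#' Define a synthetic feature panel
#'
#' Each feature has a location model
#' \eqn{\mu(x) = \mu_0 + \mu_{age}\,a + \mu_{sex}\,sex} and a log-linear
#' scale \eqn{\sigma(x) = \exp(\zeta + \eta_{age}\,a + \eta_{sex}\,sex)},
#' where `a` is age mapped to \[-1, 1\] over the cohort age range.  When
#' `nu` is finite the feature is drawn from a Box-Cox Cole-Green law with
#' relative (coefficient-of-variation) scale `sigma(x)` and skew `nu`;
#' when `nu` is `NA` the feature is Gaussian-additive with absolute scale
#' `sigma(x)`.
#'
#' @param name,category,mu0,mu_age,mu_sex,zeta,eta_age,eta_sex,nu vectors
#'   of equal length (recycled where sensible).
#' @return a `feature_panel` data frame.
#' @export
feature_panel <- function(name, category, mu0, mu_age = 0, mu_sex = 0,
                          zeta = log(0.1), eta_age = 0, eta_sex = 0, nu = NA_real_) {
  out <- data.frame(name = name, category = category, mu0 = mu0,
                    mu_age = mu_age, mu_sex = mu_sex, zeta = zeta,
                    eta_age = eta_age, eta_sex = eta_sex, nu = nu,
                    stringsAsFactors = FALSE)
  valid_cat <- c("global", "volume", "thickness", "surface_area", "other")
  stopifnot(all(out$category %in% valid_cat), !anyDuplicated(out$name))
  out$std_sex_effect <- exp(2 * out$eta_sex) - 1
  class(out) <- c("feature_panel", "data.frame")
  out
}

#' Compact 12-feature validation panel
#'
#' Four regional volumes and four surface areas with substantial sex
#' effects on log-scale (standardized sex-variance effects about
#' 0.2-0.38, male variance larger, mild right skew), and four cortical
#' thickness features with near-zero scale sex effects -- the qualitative
#' contrast between feature classes seen in adult neuroimaging panels.
#'
#' @return a `feature_panel`.
#' @export
small_panel <- function() {
  rbind(
    feature_panel(paste0("vol_", 1:4), "volume",
                  mu0 = c(6000, 7500, 5200, 8800),
                  mu_age = -0.04 * c(6000, 7500, 5200, 8800),
                  mu_sex = 0.05 * c(6000, 7500, 5200, 8800),
                  zeta = log(0.08), eta_age = c(0.03, 0.04, 0.02, 0.05),
                  eta_sex = c(0.10, 0.12, 0.14, 0.16), nu = 0.5),
    feature_panel(paste0("sa_", 1:4), "surface_area",
                  mu0 = c(2500, 3100, 1800, 4000),
                  mu_age = -0.02 * c(2500, 3100, 1800, 4000),
                  mu_sex = 0.05 * c(2500, 3100, 1800, 4000),
                  zeta = log(0.07), eta_age = c(0.02, 0.03, 0.02, 0.03),
                  eta_sex = c(0.10, 0.12, 0.15, 0.13), nu = 0.5),
    feature_panel(paste0("ct_", 1:4), "thickness",
                  mu0 = c(2.4, 2.6, 2.9, 2.2),
                  mu_age = -0.03 * c(2.4, 2.6, 2.9, 2.2),
                  mu_sex = 0.005 * c(2.4, 2.6, 2.9, 2.2),
                  zeta = log(0.05), eta_age = 0.01,
                  eta_sex = c(0, 0.01, -0.01, 0.02), nu = 1)
  )
}

#' UK-Biobank-style 208-feature panel
#'
#' Four global tissue volumes plus 68 regions x volume / thickness /
#' surface area.  Effect coefficients are synthetic calibrations chosen so
#' that standardized sex-variance effects span roughly -0.1 to +0.35 for
#' volumes and surface areas and stay within about +-0.05 for thickness.
#'
#' @return a 208-row `feature_panel`.
#' @export
ukb_panel <- function() {
  r <- seq_len(68)
  g <- (r - 1) / 67
  vol_mu0 <- 2000 + 6000 * ((7 * r) %% 68) / 68
  sa_mu0 <- 800 + 2600 * ((11 * r) %% 68) / 68
  ct_mu0 <- 2 + 1.2 * ((5 * r) %% 68) / 68
  rbind(
    feature_panel(c("GMV", "WMV", "sGMV", "Ventricles"), "global",
                  mu0 = c(6e5, 5e5, 6e4, 3e4),
                  mu_age = c(-3e4, -1.5e4, -3e3, 6e3),
                  mu_sex = c(4e4, 4e4, 4e3, 3e3),
                  zeta = log(c(0.075, 0.08, 0.07, 0.35)),
                  eta_age = c(0.03, 0.03, 0.02, 0.08),
                  eta_sex = c(0.12, 0.10, 0.08, 0.15), nu = 0.5),
    feature_panel(paste0("vol_", r), "volume", mu0 = vol_mu0,
                  mu_age = -0.04 * vol_mu0, mu_sex = 0.05 * vol_mu0,
                  zeta = log(0.09), eta_age = 0.03,
                  eta_sex = -0.05 + 0.20 * g, nu = 0.5),
    feature_panel(paste0("ct_", r), "thickness", mu0 = ct_mu0,
                  mu_age = -0.03 * ct_mu0, mu_sex = 0.005 * ct_mu0,
                  zeta = log(0.05), eta_age = 0.01,
                  eta_sex = -0.02 + 0.045 * g, nu = 1),
    feature_panel(paste0("sa_", r), "surface_area", mu0 = sa_mu0,
                  mu_age = -0.02 * sa_mu0, mu_sex = 0.05 * sa_mu0,
                  zeta = log(0.07), eta_age = 0.02,
                  eta_sex = -0.03 + 0.18 * g, nu = 0.5)
  )
}

#' Sex-dependent three-site assignment probabilities
#'
#' `"probability"` uses the stated per-sex chances (females 33 / 58.75 /
#' 8.25 % for sites A / B / C; males 33 / 8.25 / 58.75 %).  `"ratio"`
#' instead derives the probabilities that make three equal-size sites with
#' male:female compositions exactly 1:1, 1:4 and 4:1 for a half-female
#' cohort.  Both parameterizations are exposed because they are not
#' mutually consistent for a ~50/50 cohort.
#'
#' @param preset `"probability"` or `"ratio"`.
#' @return 2 x 3 matrix, rows `female` / `male`, columns sites A / B / C.
#' @export
three_site_probs <- function(preset = c("probability", "ratio")) {
  preset <- match.arg(preset)
  m <- if (preset == "probability") {
    rbind(female = c(0.33, 0.5875, 0.0825), male = c(0.33, 0.0825, 0.5875))
  } else {
    rbind(female = c(1 / 3, 8 / 15, 2 / 15), male = c(1 / 3, 2 / 15, 8 / 15))
  }
  colnames(m) <- c("A", "B", "C")
  m / rowSums(m)
}

#' Describe a synthetic-cohort experiment
#'
#' @param n_subjects cohort size.
#' @param age_range age interval (years post-conception).
#' @param sex_fraction_female proportion of females.
#' @param panel a [feature_panel()].
#' @param batch_effects `NULL`, or a list with named vectors `gamma`
#'   (additive, standardized units) and `delta` (multiplicative, positive)
#'   indexed by site label (applied to every feature), or site x feature
#'   matrices.
#' @param assignment `"three_site"` (sex-weighted probabilities),
#'   `"two_site_step"` (one balanced site plus one site whose male share is
#'   `step`), or `"balanced"`.
#' @param site_probs 2 x 3 probability matrix for `"three_site"`
#'   (see [three_site_probs()]).
#' @param step male fraction of the second site for `"two_site_step"`.
#' @param site_n per-site size for `"two_site_step"` (default
#'   `floor(n_subjects / 2)`, mirroring a two-site split with leftovers
#'   unassigned).
#' @param seed integer seed; the spec plus seed fully determines the data.
#' @return a `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 3000, age_range = c(50, 80),
                            sex_fraction_female = 0.497, panel = small_panel(),
                            batch_effects = NULL,
                            assignment = c("three_site", "two_site_step", "balanced"),
                            site_probs = three_site_probs("probability"),
                            step = 0, site_n = NULL, seed = 1) {
  assignment <- match.arg(assignment)
  stopifnot(n_subjects >= 10, diff(age_range) > 0,
            sex_fraction_female > 0, sex_fraction_female < 1,
            inherits(panel, "feature_panel"),
            step >= 0, step <= 1,
            all(site_probs >= 0), all(abs(rowSums(site_probs) - 1) < 1e-8))
  if (is.null(site_n)) site_n <- floor(n_subjects / 2)
  structure(list(n_subjects = n_subjects, age_range = age_range,
                 sex_fraction_female = sex_fraction_female, panel = panel,
                 batch_effects = batch_effects, assignment = assignment,
                 site_probs = site_probs, step = step, site_n = site_n,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Assign site labels given subject sexes; returns site factor plus the
# indices of assigned subjects (two_site_step leaves leftovers unassigned).
assign_sites <- function(sex, spec) {
  n <- length(sex)
  if (spec$assignment == "three_site") {
    u <- stats::runif(n)
    sites <- colnames(spec$site_probs)
    cf <- cumsum(spec$site_probs["female", ])
    cm <- cumsum(spec$site_probs["male", ])
    site <- ifelse(sex == 0, sites[1 + findInterval(u, cf[-3])],
                   sites[1 + findInterval(u, cm[-3])])
    return(list(site = factor(site, levels = sites), keep = seq_len(n)))
  }
  if (spec$assignment == "balanced") {
    site <- sample(c("A", "B", "C"), n, replace = TRUE)
    return(list(site = factor(site), keep = seq_len(n)))
  }
  # two_site_step: site 1 sex-balanced, site 2 with male share = step
  sn <- spec$site_n
  m1 <- floor(sn / 2); f1 <- sn - m1
  m2 <- round(spec$step * sn); f2 <- sn - m2
  males <- which(sex == 1); females <- which(sex == 0)
  if (m1 + m2 > length(males) || f1 + f2 > length(females)) {
    stop(sprintf("requested site counts (%d M, %d F) exceed available subjects (%d M, %d F)",
                 m1 + m2, f1 + f2, length(males), length(females)))
  }
  pm <- sample(males); pf <- sample(females)
  idx1 <- c(pm[seq_len(m1)], pf[seq_len(f1)])
  idx2 <- c(pm[m1 + seq_len(m2)], pf[f1 + seq_len(f2)])
  keep <- sort(c(idx1, idx2))
  site <- rep(NA_character_, n)
  site[idx1] <- "S1"; site[idx2] <- "S2"
  list(site = factor(site[keep], levels = c("S1", "S2")), keep = keep)
}

#' Generate a synthetic cohort (covariates + site labels)
#'
#' Ages are uniform over the age range, sex is Bernoulli, and sites follow
#' the spec's assignment scheme.  Fully deterministic given the spec.
#'
#' @param spec a [simulation_spec()].
#' @return a data frame with `id`, `age`, `sex`, `site` (class
#'   `sim_cohort`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex <- stats::rbinom(n, 1, 1 - spec$sex_fraction_female)
  asg <- assign_sites(sex, spec)
  out <- data.frame(id = sprintf("sub-%05d", seq_len(n))[asg$keep],
                    age = age[asg$keep], sex = sex[asg$keep],
                    site = asg$site)
  class(out) <- c("sim_cohort", "data.frame")
  attr(out, "spec") <- spec
  out
}

sim_age_c <- function(age, spec) {
  (age - mean(spec$age_range)) / (diff(spec$age_range) / 2)
}

resolve_batch_effects <- function(spec, sites, feat_names) {
  be <- spec$batch_effects
  ns <- length(sites); nf <- length(feat_names)
  if (is.null(be)) {
    return(list(gamma = matrix(0, ns, nf, dimnames = list(sites, feat_names)),
                delta = matrix(1, ns, nf, dimnames = list(sites, feat_names))))
  }
  expand <- function(x, fill) {
    if (is.matrix(x)) return(x[sites, feat_names, drop = FALSE])
    if (is.null(x)) x <- stats::setNames(rep(fill, ns), sites)
    matrix(rep(x[sites], nf), ns, nf, dimnames = list(sites, feat_names))
  }
  g <- expand(be$gamma, 0)
  d <- expand(be$delta, 1)
  stopifnot(all(d > 0))
  list(gamma = g, delta = d)
}

#' Generate feature values and ground truth for a cohort
#'
#' Features follow \eqn{y = \mu(x) + \sigma(x)(\gamma_i + \delta_i
#' \varepsilon)} with \eqn{\varepsilon \sim N(0,1)} (Gaussian features), or
#' its Box-Cox Cole-Green analogue on the z scale for panel rows with a
#' finite `nu`.  Ground-truth centiles are the realized values' centiles
#' under the no-batch generating law, \eqn{\Phi(\gamma_i + \delta_i
#' \varepsilon)}; with no injected batch effects they are exactly
#' \eqn{\Phi(\varepsilon)} and uniform.
#'
#' @param cohort a `sim_cohort`.
#' @param spec the matching [simulation_spec()].
#' @return a `synthetic_cohort`: list with `table` (a [feature_table()]),
#'   `truth` (matrices `mu`, `sigma`, `z`, `centile`), `panel`, `spec`.
#' @export
generate_features <- function(cohort, spec) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  panel <- spec$panel
  n <- nrow(cohort)
  a <- sim_age_c(cohort$age, spec)
  sites <- levels(cohort$site)
  be <- resolve_batch_effects(spec, sites, panel$name)
  si <- as.integer(cohort$site)

  mk <- function() matrix(NA_real_, n, nrow(panel), dimnames = list(NULL, panel$name))
  Y <- mk(); MU <- mk(); SIG <- mk(); ZB <- mk(); Z0 <- mk()
  for (k in seq_len(nrow(panel))) {
    p <- panel[k, ]
    mu <- p$mu0 + p$mu_age * a + p$mu_sex * cohort$sex
    sig <- exp(p$zeta + p$eta_age * a + p$eta_sex * cohort$sex)
    z0 <- stats::rnorm(n)
    zb <- be$gamma[si, k] + be$delta[si, k] * z0
    if (is.finite(p$nu)) {
      arg <- 1 + p$nu * sig * zb
      bad <- arg <= 0
      for (i in 1:50) {
        if (!any(bad)) break
        z0[bad] <- stats::rnorm(sum(bad))
        zb[bad] <- be$gamma[si[bad], k] + be$delta[si[bad], k] * z0[bad]
        arg[bad] <- 1 + p$nu * sig[bad] * zb[bad]
        bad <- arg <= 0
      }
      y <- mu * arg^(1 / p$nu)
      SIG[, k] <- mu * sig  # absolute scale (approx sd)
    } else {
      y <- mu + sig * zb
      SIG[, k] <- sig
      if (any(y <= 0)) {
        warning("feature '", p$name, "' produced non-positive values; shifting its location offset")
        shift <- 2 * abs(min(y))
        mu <- mu + shift
        y <- y + shift
      }
    }
    Y[, k] <- y; MU[, k] <- mu; ZB[, k] <- zb; Z0[, k] <- z0
  }
  tab <- feature_table(Y, data.frame(age = cohort$age, sex = cohort$sex),
                       batch = cohort$site, subject_id = cohort$id,
                       category = stats::setNames(panel$category, panel$name),
                       provenance = list(generator = "combatls-synthetic",
                                         seed = spec$seed))
  structure(list(table = tab,
                 truth = list(mu = MU, sigma = SIG, z = ZB,
                              centile = stats::pnorm(ZB),
                              # the counterfactual batch-free centile; equals
                              # `centile` when no batch effects are injected
                              centile_nobatch = stats::pnorm(Z0)),
                 panel = panel, spec = spec, cohort = cohort),
            class = "synthetic_cohort")
}

#' Run the resample-sites replication experiment
#'
#' Generates one cohort from `spec`, fits reference ("true") growth charts
#' on the unharmonized features, then for each replicate resamples the
#' synthetic site assignment (seed `base_seed + r`), harmonizes with each
#' method, refits charts on harmonized data, and summarizes per-feature
#' centile errors and sex biases.
#'
#' @param spec a [simulation_spec()] (three-site or balanced assignment).
#' @param methods harmonization methods to compare.
#' @param R number of replicates.
#' @param base_seed seed base; replicate `r` uses `base_seed + r`.
#' @param eb use empirical-Bayes shrinkage.
#' @param low,high extreme-centile cuts for the proportion-female summary.
#' @return a `replication_archive`: list of data frames `features`
#'   (replicate x method x feature rows), `categories`, `expected`
#'   (true-score extreme proportions) plus metadata.
#' @export
run_replications <- function(spec, methods = c("linear", "gam", "ls"), R = 20,
                             base_seed = spec$seed, eb = TRUE,
                             low = 0.2, high = 0.8) {
  stopifnot(R >= 1)
  sc <- generate_features(generate_cohort(spec), spec)
  X <- sc$table$covariates
  Y <- sc$table$features
  panel <- sc$panel
  feats <- panel$name
  sex <- X$sex

  chart <- function(y) {
    fit_bccg(y, X, mu_terms = chart_terms("cubic", sex = TRUE),
             sigma_terms = chart_terms("cubic", sex = TRUE),
             nu_terms = chart_terms("none", sex = FALSE))
  }
  true_models <- lapply(feats, function(k) chart(Y[, k]))
  names(true_models) <- feats
  true_cent <- vapply(feats, function(k) {
    score_bccg(true_models[[k]], Y[, k], X)$centile
  }, numeric(nrow(Y)))

  cats <- unique(panel$category)
  expected <- do.call(rbind, lapply(cats, function(cc) {
    mc <- rowMeans(true_cent[, feats[panel$category == cc], drop = FALSE])
    ep <- extreme_centile_proportions(mc, sex, low = low, high = high)
    data.frame(category = cc, expected_low = ep$prop_female_low,
               expected_high = ep$prop_female_high)
  }))

  feat_rows <- list(); cat_rows <- list()
  n_fail <- 0L; n_fit <- 0L
  for (r in seq_len(R)) {
    set.seed(base_seed + r)
    asg <- assign_sites(sex, spec)
    idx <- asg$keep
    ftr <- feature_table(Y[idx, , drop = FALSE], X[idx, , drop = FALSE],
                         batch = asg$site, subject_id = sc$table$subject_id[idx],
                         category = sc$table$category)
    for (m in methods) {
      h <- harmonize(ftr, method = m, eb = eb)
      errs <- matrix(NA_real_, length(idx), length(feats),
                     dimnames = list(NULL, feats))
      for (k in feats) {
        n_fit <- n_fit + 1L
        res <- tryCatch({
          mod <- chart(h$table$features[, k])
          cent <- score_bccg(mod, h$table$features[, k], X[idx, , drop = FALSE])$centile
          cent - true_cent[idx, k]
        }, error = function(e) { NULL })
        if (is.null(res)) { n_fail <- n_fail + 1L; next }
        errs[, k] <- res
      }
      sxe <- apply(errs, 2, function(e) {
        stats::median(e[sex[idx] == 1]) - stats::median(e[sex[idx] == 0])
      })
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        replicate = r, method = m, feature = feats, category = panel$category,
        eta_sex = panel$eta_sex, std_sex_effect = panel$std_sex_effect,
        median_abs_error = apply(abs(errs), 2, stats::median),
        sex_diff = sxe, row.names = NULL)
      for (cc in cats) {
        fk <- feats[panel$category == cc]
        mc <- rowMeans(errs[, fk, drop = FALSE] + true_cent[idx, fk, drop = FALSE],
                       na.rm = TRUE)
        ep <- extreme_centile_proportions(mc, sex[idx], low = low, high = high)
        exp_row <- expected[expected$category == cc, ]
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          replicate = r, method = m, category = cc,
          median_sex_diff = stats::median(sxe[fk]),
          low_bias = ep$prop_female_low - exp_row$expected_low,
          high_bias = ep$prop_female_high - exp_row$expected_high,
          row.names = NULL)
      }
    }
  }
  if (n_fail > 0.2 * n_fit) {
    stop(sprintf("too many model failures: %d of %d chart fits", n_fail, n_fit))
  }
  structure(list(features = do.call(rbind, feat_rows),
                 categories = do.call(rbind, cat_rows),
                 expected = expected, spec = spec, methods = methods,
                 R = R, base_seed = base_seed, n_failures = n_fail),
            class = "replication_archive")
}
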