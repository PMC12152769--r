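---
title: "Location- and scale-preserving harmonization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location- and scale-preserving harmonization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combatls)
```

## The problem

Pooling tabular features (regional brain volumes, cortical thickness,
surface areas, or any positive morphometric measurements) across scanners,
sites or studies introduces technical batch effects in both the location
and the spread of each feature.  ComBat-style harmonization estimates an
additive effect $\gamma_{ik}$ and a multiplicative effect $\delta_{ik}$
per batch $i$ and feature $k$ on standardized residuals, shrinks them
across features by empirical Bayes, and removes them while preserving
modeled covariate effects.

Classic ComBat and its spline extension preserve covariate effects on the
*mean* only: the standardization denominator is a single pooled
$\hat\sigma_k$.  When a biological covariate also changes a feature's
*variance* — sex differences in the variability of regional volumes are
the canonical example — and that covariate is unevenly distributed across
batches, pooled-scale harmonization misreads biological variance as a
batch effect and removes it.  Downstream normative (growth-chart) scores
are then distorted, asymmetrically for the over- and under-represented
groups.

## The location-scale model

For batch $i$, subject $j$, feature $k$ the package's `method = "ls"`
flavor assumes

$$y_{ijk} = \alpha_k + f_k(x_{ij}) + \gamma_{ik} + \delta_{ik}\,e_{ijk},
\qquad e_{ijk} \sim N(0, \sigma_{ijk}^2),
\qquad \log \sigma_{ijk} = \zeta_k + x_{ij}^T \eta_k,$$

i.e. the error standard deviation is log-linear in the covariates (log
link: positivity without constraints and a multiplicative, hence
scale-free, covariate effect).  Standardized data are

$$z_{ijk} = \frac{y_{ijk} - \hat\alpha_k - \hat f_k(x_{ij})}
{\exp(\hat\zeta_k + x_{ij}^T\hat\eta_k)},$$

site effects are estimated on $z$ under the usual identifiability
constraint $\sum_i n_i \hat\gamma_{ik} = 0$, shrunk via
normal/inverse-gamma empirical Bayes within feature groups, and the
harmonized observations are reconstructed as

$$y^*_{ijk} = \hat s_{ijk}\,\frac{z_{ijk} - \gamma^*_{ik}}{\delta^*_{ik}}
+ \hat\alpha_k + \hat f_k(x_{ij}),$$

the unique expression that inverts the standardization and reduces to
classic ComBat when $\hat s_{ijk} = \hat\sigma_k$.  The scale model is
made identifiable the same way as the mean model: it is first fit with
one intercept per batch and no global intercept, $\hat\zeta_k$ is
recovered as the $n_i$-weighted mean of the per-batch intercepts, and
the per-batch scale effects are deviations from that grand mean, so the
$n_i$-weighted mean of $\log\hat\delta_{ik}$ is zero per feature.

The comparison flavors differ only in their first- and second-moment
models:

| method | mean model | scale model |
|---|---|---|
| `none` | intercept (+ batch) | pooled $\hat\sigma_k$ |
| `linear` | linear age + sex | pooled $\hat\sigma_k$ |
| `gam` | penalized spline in age + linear sex | pooled $\hat\sigma_k$ |
| `ls` | penalized spline in age + linear sex | $\exp(\zeta + \eta_{age}\,a + \eta_{sex}\,s)$ |

## Numerical choices

* **Spline family.** A single basis family is used for every spline term:
  cubic B-splines with equally spaced knots extended beyond the data
  range (10 interior knots by default) and a second-order difference
  penalty, with the smoothing parameter chosen by generalized
  cross-validation on the first pass and then held fixed.  Equally spaced
  knots make linear functions exactly penalty-free, so a penalized fit on
  straight-line data reproduces the line to machine precision.  Beyond
  the training age range the spline is extended linearly (with a logged
  warning) so new subjects never hard-fail.
* **Scale-model fitting.** Maximum likelihood of the log-linear normal
  scale model by Fisher scoring with step-halving; the expected
  information is the constant matrix $2W^TW$, so each step is a single
  solve and the profile log-likelihood is non-decreasing.  Convergence is
  declared when the largest coefficient change falls below $10^{-6}$
  (at most 50 iterations).  The joint location-scale fit alternates a
  weighted least-squares mean update (weights $1/\hat s^2$) with a scale
  update until coefficients stabilize.
* **Guard against scale overfitting.** Covariate effects on $\sigma$ are
  only fit when $n \ge 10\times$ the number of scale coefficients;
  otherwise the model falls back to a constant scale with a warning.
  Preserving covariates in the second moment is easy to overfit in small
  batches, and a constant-scale fallback is the conservative default.
* **Residual variances** use the maximum-likelihood divisor $n$
  throughout, consistent with the likelihood used by the scale model.
* **Empirical Bayes.** Hyperparameters by method of moments across the
  features of a group (normal prior for $\gamma$, inverse-gamma for
  $\delta^2$); the conditional-posterior fixed point is iterated to a
  $10^{-6}$ max-change tolerance.  Degenerate groups (identical naive
  effects, so the prior has zero spread) are left unshrunk; a moment
  estimate of the inverse-gamma shape $\le 2$ (infinite prior variance)
  falls back to the naive estimates with a warning.  The default grouping
  follows the feature category map (global / volume / thickness /
  surface area) when it is informative.  $\delta^2$ is shrunk on the raw
  scale with an inverse-gamma prior, the classic ComBat convention; a
  log-scale prior would be a defensible alternative but is not what the
  surrounding ecosystem does.
* **No reference batch.** All batches are adjusted toward the pooled
  standard; a reference-batch mode is out of scope.
* **Harmonization is deterministic**; all randomness lives in the
  simulator.

## The normative engine

Growth charts use the Box-Cox Cole-Green (LMS) family:
$z = ((y/\mu)^\nu - 1)/(\nu\sigma)$ (the $\nu \to 0$ limit is
$\log(y/\mu)/\sigma$) with linear predictors for $\mu$ (identity or log
link), $\log\sigma$, and $\nu$.  Centiles are $\Phi(z)$.  The default
chart is a cubic polynomial in (standardized) age plus a linear sex term
in both $\mu$ and $\log\sigma$, with a constant $\nu$; a penalized-spline
variant with an age-by-sex interaction and per-moment batch fixed effects
is available through `chart_terms()`.  Notes:

* The positivity-truncation term of the BCCG density (the mass the
  transform would place below $y = 0$) is omitted from the likelihood,
  the standard simplification when $\sigma\nu$ is small.
* Intercepts are included in every linear predictor; a positive-location
  model without an intercept is not identifiable.
* Fitting is block-coordinate: $\mu$, $\sigma$ and $\nu$ blocks are
  updated in turn by BFGS with analytic gradients, which keeps the
  deviance non-increasing across outer iterations; if 200 outer cycles do
  not converge, a joint quasi-Newton pass over all coefficients is used
  as the fallback stepping scheme, and the convergence flag records which
  algorithm finished.
* $\nu$ is weakly identified when $\sigma$ is small (the likelihood is
  nearly flat in $\nu$), so its estimate carries a much larger sampling
  error than the $\mu$ or $\sigma$ coefficients; centile predictions are
  correspondingly insensitive to it.
* The standardized sex effect on variance is
  $(\mathrm{Var}_M - \mathrm{Var}_F)/\mathrm{Var}_F$ at a reference age
  with $\mathrm{Var} = (\mu\sigma)^2$; when the $\mu$ model has no sex
  term this reduces to $\exp(2\beta_{\sigma,sex}) - 1$.
* Significance of a $\sigma$ term is assessed by a likelihood-ratio test
  of nested fits against $\chi^2$ with the dropped-coefficient degrees of
  freedom.

## What the simulator emulates — and what it does not

`simulation_spec()` + `generate_cohort()` + `generate_features()` emulate
a large adult cohort (ages uniform on 50-80 years, ~49.7% female) whose
subjects are assigned to synthetic sites with sex-dependent weights, so
that sites are sex-imbalanced *by construction but carry no technical
effects*.  Any post-harmonization distortion of normative scores is then
attributable to covariate preservation alone.  Two assignment schemes are
built in: a three-site scheme (balanced / female-dominated /
male-dominated; both the stated per-sex probabilities 33 / 58.75 / 8.25%
and an exact-ratio variant are available, because the two
parameterizations are mutually inconsistent for a roughly half-female
cohort and neither can be derived from the other) and a two-site scheme
whose second site sweeps from all-female to all-male in 10% steps.

Features follow the generating law above; rows of the panel with a finite
`nu` are drawn from the BCCG analogue (mild right skew, realistic for
volumes and areas) with `sigma` acting as a coefficient of variation.
Ground-truth centiles are the realized values' centiles under the
no-batch generating law, so with no injected batch effects they are
exactly uniform.

Effect sizes in the bundled panels are synthetic calibrations, not
published estimates: standardized sex-variance effects
$\exp(2\eta_{sex})-1$ span roughly 0.2-0.4 for volumes and surface areas
and $|{\cdot}| \le 0.05$ for thickness, with male means ~5% larger for
volumes/areas — the qualitative contrast reported for adult cohorts,
where thickness variance is much less sex-dependent than volume or area
variance.  Ages are drawn independently of sex (the imbalance of
interest is in sex only); an age-sex confound can be added through the
panel coefficients if needed.  What passing simulations therefore show
is that the estimators recover planted structure and that scale
preservation matters exactly when scale effects exist; they do not show
anything about skew/kurtosis batch effects, longitudinal structure,
missingness, or the particular effect sizes of any real cohort.

The replication driver `run_replications()` holds the cohort and its
features fixed and resamples only the site assignment (replicate $r$
reseeds with `base_seed + r`), fits reference charts on the unharmonized
data, refits charts on each method's harmonized output, and summarizes
per-feature centile errors (harmonized minus reference centile),
per-feature sex differences in median centile error, and
extreme-centile sex composition.

### Problem sizes used by the test suite

The bundled validation runs use a 12-feature panel at $n = 3000$ with 20
site-assignment replicates, $n = 10^5$ for scale-coefficient recovery,
$n = 5000$ for chart-coefficient recovery, and 500 null simulations for
test calibration.  At these sizes the qualitative contrasts of the
full-scale design (location-scale harmonization dominating pooled-scale
methods on scale-affected features; near-parity on thickness-like
features) reproduce clearly in across-replication summaries, while
per-replicate orderings of methods on weakly affected features
(standardized effects near 0.2) remain noisy — with 20 replicates the
sex-bias t-tests have limited power, and single-replicate comparisons on
weak-effect features are within noise.  The across-replication medians
are the stable summary at this scale.

## Evaluation statistics

* **Centile error**: harmonized-data centile minus reference centile;
  positive = inflation.
* **Rank Welch tests**: absolute centile errors are pooled and converted
  to mid-ranks (average ties) before a two-tailed t-test with Welch's
  correction.  "Paired with Welch's correction" is internally
  contradictory (a paired t has no Welch degrees of freedom), so the
  paired mode is resolved as a one-sample t on within-pair rank
  differences and the Welch form is used for independent groups; the
  rank transform makes both invariant to monotone transforms of the
  scores.
* **FDR**: Benjamini-Hochberg step-up (`p.adjust`), the field default.
* **Residual site effect**: Cohen's $f^2 = (R^2_{full} -
  R^2_{reduced})/(1 - R^2_{full})$ from refitting the chart with and
  without batch fixed effects in $\mu$ and $\sigma$, where $R^2$ is the
  generalized (Nagelkerke) pseudo-$R^2$
  $1 - \exp(-\tfrac{2}{n}(\ell - \ell_{null}))$ without the Cragg-Uhler
  normalization (a `normalized = TRUE` switch applies it).  Tiny negative
  $f^2$ from finite optimization tolerances are clamped to zero.
* **Method divergence**: per-subject mean absolute centile difference
  between two harmonization methods, counts of discrepant extreme
  classifications (beyond the 5% tails by default; both cuts are
  configurable), and a companion regression of the divergence on batch
  mean age, batch age range and the subject's own age deviation,
  controlling for batch size.
* **QC filters**: the Euler-style quality cut excludes values more than
  $k = 2$ *unscaled* MADs above the within-group median (upper side
  only); the biological-plausibility guard excludes values more than
  $k = 20$ unscaled MADs from the feature median (two-sided).  The MAD is
  left unscaled (no 1.4826 consistency factor) — a deliberate, recorded
  choice since either convention is defensible; both multipliers are
  arguments.

## Known limitations

* Only first and second moments are modeled: batch effects in skew or
  kurtosis pass through, and covariate effects on higher moments are not
  preserved.
* Covariates must be pre-specified; the scale model defaults to age +
  sex and silently preserves only what it is told to model.
* Batches need at least 3 subjects, and genuinely informative scale
  preservation needs considerably more; the $n \ge 10p$ guard is a floor,
  not a recommendation.
* The BCCG engine fits single features independently; multivariate
  (covariance) harmonization is a different method family and is out of
  scope, as are latent-space and longitudinal variants.
* `mu_link = "identity"` charts can in principle predict non-positive
  $\mu$ far outside the training range; the log link (or log-transformed
  harmonization, `log_transform = TRUE`) is the robust choice for
  strictly positive features.
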