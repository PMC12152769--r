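# combatls

Location- **and scale-**preserving multi-site harmonization for tabular
features, with a normative-scoring (growth-chart) engine and a simulation
framework for validating harmonization methods on sex-imbalanced sites.

## The problem

Multi-site studies harmonize features across scanners or studies with
ComBat-family methods: per-batch additive (γ) and multiplicative (δ)
effects are estimated on standardized data, shrunk across features by
empirical Bayes, and removed, while modeled covariate effects are
preserved. Classic ComBat and its spline extension preserve covariate
effects on the **mean** only. But biological covariates — sex and age
foremost — also shape features' **variances**. When such covariates are
unevenly distributed across sites (a male-dominated and a
female-dominated site, say), pooled-variance harmonization mistakes
biological variance for a batch effect and removes it, which distorts
downstream normative scores (centiles, z-scores) asymmetrically by group.

The location-scale method implemented here (`method = "ls"`) models each
feature as

    y_ijk = α_k + f_k(x_ij) + γ_ik + δ_ik e_ijk,   e_ijk ~ N(0, σ_ijk²)
    log σ_ijk = ζ_k + x_ij' η_k

so the standardization denominator `exp(ζ̂ + x'η̂)` carries the covariate
effects on scale through harmonization. With `ŝ = σ̂_k` (pooled) the same
code path reduces to classic ComBat (`linear`) or its spline-mean variant
(`gam`). Harmonized observations are

    y* = ŝ(x) · (z − γ*) / δ* + α̂ + f̂(x).

The package also provides:

* a Box-Cox Cole-Green (LMS) normative engine — `fit_bccg()`,
  `score_bccg()` — for centiles and z-scores against age/sex growth
  charts, with sex-variance effect summaries and sigma-term
  likelihood-ratio tests;
* a synthetic-cohort simulator — `simulation_spec()`,
  `generate_cohort()`, `generate_features()`, `run_replications()` —
  reproducing sex-imbalanced synthetic-site designs with known ground
  truth;
* evaluation statistics — centile errors, rank-based Welch tests,
  sex-bias summaries, extreme-centile proportions, Benjamini-Hochberg
  FDR, residual-site-effect sizes (Cohen's f²), method divergence;
* CSV/TSV ingestion with listwise deletion, MAD-based QC filters, and a
  thin command-line wrapper (`inst/exec/combatls.R`).

## Worked example

Simulate a cohort assigned to three sex-imbalanced sites (one balanced,
one 1:4 and one 4:1 male:female), harmonize with the pooled-scale and
location-scale methods, and compare how well each preserves the sex
effect on variance:

```r
library(combatls)

spec <- simulation_spec(n_subjects = 3000, seed = 1)   # 12-feature panel
sc   <- generate_features(generate_cohort(spec), spec)
print(sc$table)
#> feature_table: 3000 subjects x 12 features, 3 batch(es)
#>   categories: surface_area=4, thickness=4, volume=4
#>   age range: 50.02-80.00; 50.2% female

h_ls  <- harmonize(sc$table, method = "ls")
h_gam <- harmonize(sc$table, method = "gam")

# fit growth charts and read off the standardized sex effect on variance
eff <- sapply(list(true = sc$table, gam = h_gam$table, ls = h_ls$table),
  function(tab) {
    m <- fit_bccg(tab$features[, "vol_4"], tab$covariates)
    sex_variance_effect(m)
  })
round(eff, 3)
#>  true   gam    ls
#> 0.604 0.368 0.592
```

The generating model gave `vol_4` a standardized sex-variance effect of
`exp(2 * 0.16) - 1 = 0.377` plus a 5% male mean offset (realized
variance effect ≈ 0.5-0.6). Pooled-scale harmonization (`gam`)
attenuates it toward zero; the location-scale method preserves it. Centile-level consequences are quantified by the
replication driver:

```r
arch <- run_replications(spec, methods = c("linear", "gam", "ls"), R = 20)
aggregate(median_abs_error ~ method + category, arch$features, median)
#>   method     category median_abs_error
#>      gam surface_area          0.00616
#>   linear surface_area          0.00614
#>       ls surface_area          0.00345
#>      gam    thickness          0.00328
#>   linear    thickness          0.00331
#>       ls    thickness          0.00315
#>      gam       volume          0.00638
#>   linear       volume          0.00639
#>       ls       volume          0.00345
```

Median absolute centile errors (in centile units, 0-1) on scale-affected
features are roughly halved by the location-scale method; on
thickness-like features (no scale-sex effect) the methods are close.

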