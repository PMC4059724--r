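# rainweibull

Diameter-distribution modelling for even-aged plantations with
environment-driven Weibull parameters, built around black wattle
(*Acacia mearnsii*) chronosequences.

## What problem this solves, and for whom

Forest managers and biometricians need the diameter distribution of a
stand — the frequency of trees per diameter-at-breast-height (DBH) class —
to plan harvests and predict product yields. Where inventory history is
missing, a *parameter prediction* model lets you reconstruct the
distribution from covariates you do have. `rainweibull` implements the full
workflow: fit candidate probability density functions to tree lists, select
one by goodness of fit, track how the distribution's shape evolves with
stand age, relate the fitted parameters to meteorological and soil
covariates, and distil the result into a model in which both Weibull
parameters are linear in accumulated rainfall.

## The core model

The DBH distribution of a stand is a two-parameter Weibull with shape
γ and scale β (cm):

    f(x) = (γ/β) (x/β)^(γ−1) exp(−(x/β)^γ)

and both parameters are predicted from accumulated rainfall `Prec`
(mm, planting to measurement):

    γ = 5.62235 − 0.00020493 · Prec
    β = 4.29692 + 0.00106  · Prec

valid while both predictors stay positive (Prec ∈ (0, 27435] mm). The
defaults are the black wattle estimates; all four coefficients are
configurable and re-estimable from data via `estimate_rainfall_model()`.

## Worked example

```r
library(rainweibull)

m <- rainfall_weibull_model()
m
#> Rainfall-driven Weibull model
#>   shape: 5.62235 -0.00020493 * Prec
#>   scale: 4.29692 +0.00106 * Prec
#>   valid Prec range: (0, 27435.5] mm

# a 7-year-old stand that received 1350 mm/yr: Prec = 9450 mm
predict_params(m, 1350 * 7)
#>     shape     scale
#>  3.685761 14.313920
```

The predicted scale (≈14.3 cm) is the characteristic diameter of the
stand — the 63rd percentile of DBH; shape ≈3.7 gives a mildly
left-skewed, unimodal distribution typical of closed-canopy plantations.

Contrast a dry and a wet regime at rotation age:

```r
simulate_scenarios(m, annual_levels = c(800, 1500), ages = 7)
#> Rainfall scenario simulation: 2 scenarios (0 invalid)
#>  annual_rainfall_mm age_years accumulated_mm  shape   scale mean_dbh
#>                 800         7           5600 4.4747 10.2329     9.34
#>                1500         7          10500 3.4706 15.4269    13.87
```

Under the wet regime the mean DBH at age 7 is 13.9 cm versus 9.3 cm when
dry: rainfall shifts the whole distribution toward larger diameter classes
(each scenario also carries the per-2-cm-class probabilities).

The synthetic-study generator reproduces the reference sampling design
(2 sites × 4 ages, 765 trees), and direct fitting recovers the generating
parameters:

```r
study <- generate_study(wattle_study_design(),
                        params_by_age = wattle_age_coefficients())
f <- fit_mle(study$trees$dbh_cm[study$trees$age_years == 7], "weibull2")
f
#> Maximum-likelihood fit: weibull2 (n = 160)
#>     shape     scale
#>  4.339515 14.340077
#> log-likelihood: -423.0402
ks_one_sample(study$trees$dbh_cm[study$trees$age_years == 7], f)
#> KS = 0.03433, alpha = 0.05: not significant (p = 0.9917)
```

`run_pipeline(pipeline_config(seed = 42L))` executes every stage —
fitting, KS/AD/CvM selection, shape tables, covariate correlations,
stepwise regression with diagnostics, the dummy-variable site test,
rainfall-model re-estimation, predicted-vs-fitted validation and scenario
simulation — writing each table as CSV with a manifest.

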