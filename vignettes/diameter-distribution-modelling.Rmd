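---
title: "Rainfall-driven diameter-distribution modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rainfall-driven diameter-distribution modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rainweibull)
```

## The problem and the model

The diameter distribution of an even-aged plantation — the relative
frequency of trees per diameter-at-breast-height (DBH) class — summarises
its structure, its wood stock by product class, and its stage of
development. `rainweibull` implements a *parameter prediction* approach for
black wattle (*Acacia mearnsii*) chronosequences: the stand's DBH
distribution is described by a two-parameter Weibull,

$$f(x) = \frac{\gamma}{\beta}\left(\frac{x}{\beta}\right)^{\gamma-1}
e^{-(x/\beta)^\gamma}, \qquad x \ge 0,$$

with shape $\gamma$ and scale $\beta$ (cm), and both parameters are in turn
modelled as linear functions of the accumulated rainfall $Prec$ (mm, summed
from planting to the measurement date):

$$\gamma = a_\gamma + b_\gamma\,Prec, \qquad \beta = a_\beta + b_\beta\,Prec.$$

The bundled default coefficients are the estimates for black wattle stands
in Rio Grande do Sul, Brazil ($\gamma = 5.62235 - 0.00020493\,Prec$,
$\beta = 4.29692 + 0.00106\,Prec$). With them the model predicts a whole
diameter distribution from rainfall records alone, which supports growth
simulation where no inventory history exists. All four coefficients are
configurable, and `estimate_rainfall_model()` refits them from any
per-stand estimator panel, so the bundled instance and the method are
separable.

A note on symbols: in parts of the forestry literature the labels attached
to $\gamma$ and $\beta$ are inconsistent. This package fixes the
parameterization by the CDF $F(x) = 1 - e^{-(x/\beta)^\gamma}$, i.e.
$\gamma$ is always the (dimensionless) shape and $\beta$ the scale in cm.
The bundled per-age coefficients only make sense in this orientation: the
scale tracks the mean DBH from 5.6 to 14.1 cm as stands age from 1 to 7
years while the shape stays near 4, and the closed-form mean
$\beta\,\Gamma(1+1/\gamma)$ then reproduces the per-age observed means to
within 0.1%.

## Pipeline stages

`run_pipeline()` executes the full analysis in the order a field study
would:

1. **Candidate fitting** (`fit_mle`): normal, lognormal, two-parameter
   gamma, and two- and three-parameter Weibull, all by maximum likelihood
   on the raw (unbinned) diameters, per stand age.
2. **Selection** (`ks_one_sample`, `select_distribution`): one-sample
   Kolmogorov–Smirnov at 5%; among the non-rejected families the
   two-parameter Weibull is preferred because its two estimators are the
   quantities related to environmental covariates downstream. The
   Anderson–Darling and Cramér–von Mises statistics confirm the selection.
3. **Shape dynamics** (`shape_summary`, `shape_table`): mean, extremes,
   median, modal-class mode, bias-adjusted skewness and kurtosis, and the
   asymmetry/kurtosis classifications, per age.
4. **Environmental modelling** (`estimator_panel`, `correlate_estimators`,
   `stepwise_select`, `dummy_site_model`): Pearson correlations of
   $\hat\gamma$ and $\hat\beta$ with meteorological accumulations and
   surface-soil chemistry; forward stepwise regression with a diagnostic
   battery; a dummy-variable test of whether the rainfall relationship
   differs between planting sites.
5. **Prediction and simulation** (`estimate_rainfall_model`,
   `compare_predicted_vs_fitted`, `simulate_scenarios`): re-estimated
   rainfall equations, curve-vs-curve validation by two-sample KS, and
   diameter-class probability tables under alternative rainfall regimes.

## Goodness-of-fit: statistics, calibration, conventions

The three one-sample EDF statistics are computed from their defining sums
on the ordered sample ($D$, $A^2$, $W^2$). Two calibration modes exist for
KS, because they answer different questions:

* `asymptotic` (default) applies the known-parameter Kolmogorov
  distribution to $\sqrt{n}\,D$ even though the parameters were estimated
  from the same sample. This is the long-standing convention of
  distribution-fitting procedures in mainstream statistical software and is
  what classical published decision tables reflect; with estimated
  parameters it is conservative (true rejection rate below the nominal
  $\alpha$), which the test suite verifies by simulation.
* `bootstrap` calibrates the null correctly: each of $B$ parametric
  resamples from the fitted model is refitted and the statistic's null
  distribution is taken from those replicates. The AD and CvM decisions
  always use this parametric bootstrap (default $B = 999$; the pipeline
  default is smaller because those tests only confirm an already-made
  selection).

CDF values that are numerically 0 or 1 are clamped to
$[10^{-12}, 1-10^{-12}]$ (with a warning) before the $A^2$ logarithms.

Curve-vs-curve comparisons (`ks_two_sample`) evaluate both CDFs on a 0.01 cm
grid over $[0, 1.5\times]$ the larger scale, take the sup gap, and use the
large-sample critical value $c(\alpha)\sqrt{(n_a+n_b)/(n_a n_b)}$. Fitted
curves carry no sample size of their own, so the effective sizes default to
the tree counts of the stands behind them; this convention is what makes a
significance statement about two fitted curves meaningful at all, and the
output records it.

## Distribution fitting details

* Weibull and gamma fits run through `fitdistrplus::fitdist` with
  moment-based starting values (shape from the coefficient-of-variation
  approximation $cv^{-1.086}$, clamped to $[0.2, 50]$); normal and
  lognormal use their closed-form MLEs with the divide-by-$n$ variance.
* The three-parameter Weibull location is estimated by profile likelihood:
  Brent searches over the location (three starts across
  $(\min(x) - 2\,\mathrm{range}, \min(x) - 10^{-6})$, guarding against flat
  profiles near the sample minimum) with a two-parameter inner fit on the
  shifted sample. Direct trivariate optimisation is unstable when the
  location approaches the minimum; the profile is not.
* Degenerate samples (zero spread), non-finite values, and $n < 10$ are
  rejected up front.

## Shape statistics: estimators and conventions

Skewness is the bias-adjusted sample coefficient
$g_1\sqrt{n(n-1)}/(n-2)$ and kurtosis the bias-adjusted excess (both via
`e1071`, type 2 — the estimators mainstream statistical packages print).
The asymmetry bands are $|g| < 0.15$ symmetric, $0.15$–$1$ moderate, $>1$
strong, with direction from the standard sign convention (positive = right
tail; equivalently mode < median < mean). Some field literature words the
directions the other way around; this package keeps the standard convention
and reports the mean/median/mode ordering so no reader needs to guess.

Kurtosis classification supports two conventions that do **not** coincide
on real samples: the percentile coefficient $(Q_3-Q_1)/(2(P_{90}-P_{10}))$
compared against its normal value 0.263 (below = leptokurtic), and the
moment convention by the sign of excess kurtosis. Field tables often print
moment excess while stating the 0.263 rule; because the two conventions can
classify the same sample differently, `classify_kurtosis()` requires the
caller to name the convention, and `shape_summary` reports both
coefficients.

The mode of a continuous diameter sample is defined as the midpoint of the
most populated 2 cm class (ties to the lowest class). This estimator is
deterministic and matches how stand tables are read in practice; published
mode values computed by unstated estimators are not reproducible from it.
When a sample undershoots the 1 cm class origin, the modal-class grid
extends downward in whole class widths; `bin_diameters` itself refuses such
values, since an analysis that bins diameters should choose its origin
explicitly.

## Regression and stepwise conventions

`ols_diagnose` wraps `lm` and always computes: Durbin–Watson (via `lmtest`),
the White test as $nR^2$ of the auxiliary regression of squared residuals
on regressors, squares and cross-products — falling back to the
no-cross-product variant whenever the auxiliary design would exhaust the
residual degrees of freedom, which is routine with eight stands —
Shapiro–Wilk on residuals, and VIFs from the auxiliary-regression
definition $1/(1-R_j^2)$ (tolerance $=1/\mathrm{VIF}$). VIF > 10 is the
multicollinearity flag used when interpreting stepwise output.

Stepwise selection is forward with replacement: entry by the smallest
partial-$F$ $p$-value under `alpha_enter` = 0.15, removal of any term whose
partial $p$ rises above `alpha_stay` = 0.15, and a stricter reporting
screen (`report_alpha` = 0.01) flagging which final coefficients survive at
1%. The 0.15/0.15 defaults are the common stepwise convention; the 1%
screen is what decides which published-style equation is retained. With
eight stands, later-entering terms routinely fail the 1% screen even when
they raise $R^2$ — the expected behaviour, not an error.

The site test fits $y = b_0 + b_1 D + b_2 x + b_3 D x$ with $D$ the 0/1
site indicator and tests $b_1 = b_3 = 0$ jointly by the extra
sum-of-squares $F$ test at 5%. Non-significance licenses pooling both sites
into one rainfall equation.

## The synthetic study: what it emulates, what it does not

`wattle_study_design()` reproduces the reference chronosequence exactly as
a sampling design: 2 sites × 4 ages (1, 3, 5, 7 years), per-stand tree
counts 112/100/90/77 (Cristal) and 107/106/90/83 (Piratini), totalling 765
trees; 3 × 1.75 m spacing (1904 stems/ha) at age 1 and 3 × 1.5 m
(2222 stems/ha) otherwise. Diameters are i.i.d. Weibull draws, either from
the per-age reference coefficients or from the rainfall model. Defaults
chosen once and documented here: annual rainfall 1350 mm/yr (Cristal) and
1200 mm/yr (Piratini), inside the regional 1200–1350 mm/yr envelope and
distinct so the two sites are distinguishable; accumulated rainfall is
annual × age, the only reading under which the scale equation traverses the
observed 5.6→14.1 cm range over a rotation. Solar radiation accumulates
with age (5500 MJ m⁻² yr⁻¹ ± 5%); temperatures and humidity vary around
subtropical normals; the 13 soil-chemistry variables are drawn from uniform
ranges typical of acid subtropical surface horizons. Real soil values were
never published, so these exist to exercise the correlation/stepwise
machinery, not to be realistic per-site values.

What the generator does *not* emulate — and hence what green tests do not
establish about field data: spatial structure and slope-position effects
(the three plots per stand are collapsed to one label), mortality and
ingrowth, measurement error, within-stand diameter autocorrelation, and any
real meteorological time series (the Angstrom–Prescott radiation helper
takes caller-supplied calibration coefficients; no site calibration is
assumed). Passing tests show the *machinery* is correct under the stated
distributional assumptions, not that black wattle diameters are Weibull.

## Numerical choices

* Binning uses half-open $[l, u)$ classes so no diameter is double-counted;
  a value exactly on the top break opens one more class.
* The rainfall model's valid domain is where both linear predictors are
  positive — $(0, 27435]$ mm for the defaults, the shape reaching zero
  first. Out-of-range scenarios become per-cell error entries; a scenario
  run never aborts wholesale.
* Predicted-mean monotonicity in rainfall holds over the whole valid range,
  but strict first-order stochastic dominance between two predicted curves
  fails in the extreme lower tail (below ≈2.5 cm the two CDFs cross at
  ~$10^{-3}$ mass) because the shape falls as the scale rises; dominance
  statements are therefore made over the diameter-class range.
* Every stochastic stage derives from an explicit seed (`withr::with_seed`
  scoping, so library calls never disturb the caller's RNG), and the
  pipeline is byte-deterministic for a fixed configuration.
* Bootstrap defaults: $B = 999$ for standalone confirmation tests; the
  pipeline confirmation stage defaults to $B = 199$ and the test suite uses
  $B = 99$ with 200 replicates for calibration checks — sizes at which the
  binomial sampling band around the nominal level is already narrow enough
  to detect a miscalibrated test.
* Parameter-recovery checks use $n = 2\times10^5$ draws (coefficients
  recovered within 1.5%) and Monte-Carlo moment checks $n = 10^6$.

## Known limitations

The rainfall equations are a two-site, four-age instance: eight stands give
eight panel points, so the stepwise stage can saturate quickly, the White
test usually needs its reduced variant, and re-estimated coefficients carry
wide (unreported) uncertainty. The model ignores every water-balance
mechanism (soil storage, evapotranspiration); rainfall is a proxy, and
extrapolation beyond the fitted rainfall range (roughly 1200–9450 mm
accumulated) is unguarded by anything except the positivity domain.
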