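#' Rainfall-driven Weibull parameter-prediction model
#'
#' The parameter prediction model at the core of the package: both
#' parameters of the two-parameter Weibull diameter distribution are linear
#' in accumulated rainfall `Prec` (mm, planting to measurement):
#' \deqn{\gamma = a_\gamma + b_\gamma \cdot Prec, \qquad
#'       \beta = a_\beta + b_\beta \cdot Prec.}
#' The defaults are the coefficients estimated for black wattle
#' chronosequences in Rio Grande do Sul
#' (\eqn{\gamma = 5.62235 - 0.00020493\,Prec},
#' \eqn{\beta = 4.29692 + 0.00106\,Prec}); all four are overridable, and
#' [estimate_rainfall_model()] refits them from any estimator panel. The
#' valid rainfall range is where both linear predictors stay positive —
#' `(0, 27435]` mm for the defaults, the shape hitting zero first.
#'
#' @param gamma_intercept,gamma_slope Shape intercept and slope (per mm).
#' @param beta_intercept,beta_slope Scale intercept (cm) and slope (cm/mm).
#' @return Object of class `rainfall_weibull` with the coefficients and the
#'   derived `valid_range` (mm).
#' @examples
#' m <- rainfall_weibull_model()
#' predict_params(m, 1000)
#' @export
rainfall_weibull_model <- function(gamma_intercept = 5.62235,
                                   gamma_slope = -0.00020493,
                                   beta_intercept = 4.29692,
                                   beta_slope = 0.00106) {
  lims <- function(a, b) {
    # a + b * prec > 0
    if (b == 0) {
      if (a <= 0) stop("degenerate model: constant non-positive predictor")
      c(-Inf, Inf)
    } else if (b < 0) c(-Inf, -a / b) else c(-a / b, Inf)
  }
  lg <- lims(gamma_intercept, gamma_slope)
  lb <- lims(beta_intercept, beta_slope)
  valid <- c(max(0, lg[1], lb[1]), min(lg[2], lb[2]))
  if (valid[1] >= valid[2]) stop("model has no valid rainfall range")
  structure(list(gamma_intercept = gamma_intercept, gamma_slope = gamma_slope,
                 beta_intercept = beta_intercept, beta_slope = beta_slope,
                 valid_range = valid),
            class = "rainfall_weibull")
}

#' @export
print.rainfall_weibull <- function(x, ...) {
  cat(sprintf("Rainfall-driven Weibull model\n  shape: %g %+g * Prec\n  scale: %g %+g * Prec\n  valid Prec range: (%g, %g] mm\n",
              x$gamma_intercept, x$gamma_slope, x$beta_intercept, x$beta_slope,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Predict Weibull parameters from accumulated rainfall
#'
#' @param model A `rainfall_weibull` model.
#' @param accumulated_mm Accumulated rainfall (mm) since planting; must lie
#'   inside the model's valid range, else a domain error reports the
#'   admissible interval and which parameter would turn non-positive.
#' @return Named numeric `c(shape = , scale = )` (a 2-column matrix for
#'   vector input).
#' @export
predict_params <- function(model, accumulated_mm) {
  stopifnot(inherits(model, "rainfall_weibull"))
  v <- model$valid_range
  shape <- model$gamma_intercept + model$gamma_slope * accumulated_mm
  scale <- model$beta_intercept + model$beta_slope * accumulated_mm
  bad <- accumulated_mm <= v[1] | accumulated_mm > v[2] | shape <= 0 | scale <= 0
  if (any(bad)) {
    culprit <- if (any(shape[bad] <= 0)) "shape" else "scale"
    stop(sprintf(
      "accumulated rainfall %g mm outside the model's valid range (%g, %g] mm (predicted %s would be non-positive)",
      accumulated_mm[bad][1], v[1], v[2], culprit))
  }
  if (length(accumulated_mm) == 1) c(shape = shape, scale = scale)
  else cbind(shape = shape, scale = scale)
}

#' Diameter density predicted from accumulated rainfall
#'
#' @inheritParams predict_params
#' @param x Diameter at breast height (cm), non-negative.
#' @return Weibull density at `x` under the rainfall-predicted parameters.
#' @export
predicted_pdf <- function(model, accumulated_mm, x) {
  p <- predict_params(model, accumulated_mm)
  weibull2_pdf(x, p[["shape"]], p[["scale"]])
}

predicted_cdf_fun <- function(model, accumulated_mm) {
  p <- predict_params(model, accumulated_mm)
  function(q) stats::pweibull(q, p[["shape"]], p[["scale"]])
}

#' Simulate diameter distributions under rainfall scenarios
#'
#' Evaluates the rainfall model over a grid of annual rainfall regimes and
#' stand ages (accumulated rainfall = annual level times age in whole
#' years), returning predicted parameters and the probability mass per
#' diameter class. A scenario whose accumulated rainfall falls outside the
#' model's valid range becomes an error entry; the run continues.
#'
#' @param model A `rainfall_weibull` model.
#' @param annual_levels Annual rainfall regimes in mm/yr (default the
#'   reference scenario set 800, 1100, 1300, 1500).
#' @param ages Stand ages in years (default 1, 3, 5, 7).
#' @param class_width,origin Diameter-class convention (2 cm from 1 cm).
#' @param max_dbh Upper end of the class grid (cm).
#' @return Object of class `scenario_results`: list with `scenarios` (one
#'   element per level-age pair: `annual_rainfall_mm`, `age_years`,
#'   `accumulated_mm`, `shape`, `scale`, `classes` data.frame with
#'   `probability`, or `error` message) and `summary` data.frame.
#' @examples
#' s <- simulate_scenarios(rainfall_weibull_model())
#' s$summary
#' @export
simulate_scenarios <- function(model, annual_levels = c(800, 1100, 1300, 1500),
                               ages = c(1, 3, 5, 7),
                               class_width = 2, origin = 1, max_dbh = 41) {
  if (any(annual_levels <= 0) || any(ages <= 0)) {
    stop("annual rainfall levels and ages must be positive")
  }
  breaks <- seq(origin, max_dbh, by = class_width)
  grid <- expand.grid(annual_rainfall_mm = annual_levels, age_years = ages,
                      KEEP.OUT.ATTRS = FALSE)
  scenarios <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lev <- grid$annual_rainfall_mm[i]; age <- grid$age_years[i]
    acc <- lev * age
    res <- try(predict_params(model, acc), silent = TRUE)
    if (inherits(res, "try-error")) {
      scenarios[[i]] <- list(annual_rainfall_mm = lev, age_years = age,
                             accumulated_mm = acc,
                             error = conditionMessage(attr(res, "condition")))
      rows[[i]] <- data.frame(annual_rainfall_mm = lev, age_years = age,
                              accumulated_mm = acc, shape = NA_real_,
                              scale = NA_real_, mean_dbh = NA_real_)
      next
    }
    pr <- stats::pweibull(breaks[-1], res[["shape"]], res[["scale"]]) -
      stats::pweibull(breaks[-length(breaks)], res[["shape"]], res[["scale"]])
    classes <- data.frame(class_lower = breaks[-length(breaks)],
                          class_upper = breaks[-1],
                          midpoint = breaks[-length(breaks)] + class_width / 2,
                          probability = pr)
    scenarios[[i]] <- list(annual_rainfall_mm = lev, age_years = age,
                           accumulated_mm = acc, shape = res[["shape"]],
                           scale = res[["scale"]], classes = classes)
    rows[[i]] <- data.frame(annual_rainfall_mm = lev, age_years = age,
                            accumulated_mm = acc, shape = res[["shape"]],
                            scale = res[["scale"]],
                            mean_dbh = weibull_moments(res[["shape"]],
                                                       res[["scale"]])$mean)
  }
  structure(list(scenarios = scenarios, summary = do.call(rbind, rows)),
            class = "scenario_results")
}

#' @export
print.scenario_results <- function(x, ...) {
  n_err <- sum(!vapply(x$scenarios, function(s) is.null(s$error), logical(1)))
  cat(sprintf("Rainfall scenario simulation: %d scenarios (%d invalid)\n",
              length(x$scenarios), n_err))
  print(transform(x$summary, shape = round(shape, 4), scale = round(scale, 4),
                  mean_dbh = round(mean_dbh, 2)), row.names = FALSE)
  invisible(x)
}

#' Compare a rainfall-predicted curve with a directly fitted one
#'
#' Evaluates whether the diameter distribution predicted from accumulated
#' rainfall differs from the distribution fitted directly to the stand's
#' diameters, by the two-sample Kolmogorov-Smirnov test on the two curves.
#'
#' @param model A `rainfall_weibull` model.
#' @param accumulated_mm Accumulated rainfall of the stand (mm).
#' @param fitted A `fitted_dist` from the direct fit.
#' @param n_eff Effective sample size (trees measured in the stand); used
#'   for both curves.
#' @param alpha Significance level (default 0.01).
#' @return A `gof_result` from [ks_two_sample()].
#' @export
compare_predicted_vs_fitted <- function(model, accumulated_mm, fitted, n_eff,
                                        alpha = 0.01) {
  p <- predict_params(model, accumulated_mm)
  grid_max <- 1.5 * max(p[["scale"]], curve_spread(fitted))
  ks_two_sample(predicted_cdf_fun(model, accumulated_mm), fitted,
                n_eff_a = n_eff, n_eff_b = n_eff, alpha = alpha,
                grid = seq(0, grid_max, by = 0.01))
}

#' Re-estimate the rainfall model from an estimator panel
#'
#' Fits the two linear predictors (`gamma_hat` and `beta_hat` on
#' accumulated rainfall) by OLS on a per-stand estimator panel, returning a
#' new `rainfall_weibull` model plus both diagnostic fits.
#'
#' @param panel An [estimator_panel()] with a `prec_mm` column.
#' @return List: `model` (the refitted `rainfall_weibull`), `gamma_fit`,
#'   `beta_fit` (the two [ols_diagnose()] results).
#' @export
estimate_rainfall_model <- function(panel) {
  gf <- ols_diagnose(gamma_hat ~ prec_mm, panel)
  bf <- ols_diagnose(beta_hat ~ prec_mm, panel)
  model <- rainfall_weibull_model(
    gamma_intercept = gf$coefficients["(Intercept)", "estimate"],
    gamma_slope = gf$coefficients["prec_mm", "estimate"],
    beta_intercept = bf$coefficients["(Intercept)", "estimate"],
    beta_slope = bf$coefficients["prec_mm", "estimate"]
  )
  list(model = model, gamma_fit = gf, beta_fit = bf)
}
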