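panel_from_model <- function(noise_sd = 0, seed = 1, model = rainfall_weibull_model()) {
  # per-stand estimator panel built directly from the rainfall equations
  set.seed(seed)
  designs <- wattle_study_design(seed = seed)
  rows <- lapply(designs, function(d) {
    prec <- d$annual_rainfall_mm * d$age_years
    p <- predict_params(model, prec)
    data.frame(site_id = d$site_id, age_years = d$age_years,
               gamma_hat = p[["shape"]] + rnorm(1, 0, noise_sd),
               beta_hat = p[["scale"]] + rnorm(1, 0, noise_sd),
               prec_mm = prec)
  })
  do.call(rbind, rows)
}

test_that("correlations recover constructed relationships", {
  panel <- panel_from_model()
  panel$self <- panel$gamma_hat
  out <- correlate_estimators(panel, c("self", "prec_mm"))
  expect_equal(out$r_gamma[out$variable == "self"], 1)
  # beta exactly linear in rainfall with no noise
  expect_equal(out$r_beta[out$variable == "prec_mm"], 1)
  expect_equal(out$r_gamma[out$variable == "prec_mm"], -1)

  # small noise: rainfall still dominates, sign as in the reference study
  noisy <- panel_from_model(noise_sd = 0.01 * diff(range(panel$beta_hat)),
                            seed = 4)
  r <- correlate_estimators(noisy, "prec_mm")
  expect_gt(r$r_beta, 0.9)
  expect_lt(r$r_gamma, -0.9)

  # zero-variance covariate: undefined, not an error
  panel$flat <- 7
  out <- correlate_estimators(panel, c("flat", "prec_mm"))
  expect_true(is.na(out$r_gamma[out$variable == "flat"]))

  expect_error(correlate_estimators(panel[1:2, ]), "at least 3")
})

test_that("OLS reproduces textbook closed forms and exact recovery", {
  # hand-computable 3-point dataset
  d <- data.frame(x = c(0, 1, 2), y = c(1, 3, 4))
  o <- oracle_ols_simple(d$x, d$y)
  f <- ols_diagnose(y ~ x, d)
  expect_equal(f$coefficients["(Intercept)", "estimate"], unname(o["intercept"]))
  expect_equal(f$coefficients["x", "estimate"], unname(o["slope"]))

  # noiseless points from the reference rainfall equations: 1e-8 recovery
  prec <- c(1200, 1350, 3600, 4050, 6000, 6750, 8400, 9450)
  db <- data.frame(prec_mm = prec,
                   beta = 4.29692 + 0.00106 * prec,
                   gamma = 5.62235 - 0.00020493 * prec)
  fb <- ols_diagnose(beta ~ prec_mm, db)
  expect_equal(fb$coefficients["(Intercept)", "estimate"], 4.29692,
               tolerance = 1e-8)
  expect_equal(fb$coefficients["prec_mm", "estimate"], 0.00106,
               tolerance = 1e-8)
  fg <- ols_diagnose(gamma ~ prec_mm, db)
  expect_equal(fg$coefficients["(Intercept)", "estimate"], 5.62235,
               tolerance = 1e-8)
  expect_equal(fg$r_squared, 1)

  # recovery is invariant to predictor scaling
  db$prec_km <- db$prec_mm / 1e6
  fk <- ols_diagnose(beta ~ prec_km, db)
  expect_equal(fk$coefficients["prec_km", "estimate"], 0.00106 * 1e6,
               tolerance = 1e-6)

  expect_error(ols_diagnose(y ~ x1 + x2, data.frame(x1 = 1:4, x2 = 2 * (1:4),
                                                    y = rnorm(4))),
               "singular|collinear")
})

test_that("regression diagnostics behave as defined", {
  expect_equal(rainweibull:::durbin_watson_stat(c(1, 1, 1, 1)), 0)

  # orthogonal two-predictor design: VIF exactly 1 for both
  d <- data.frame(x1 = c(-1, -1, 1, 1, 0, 0), x2 = c(-1, 1, -1, 1, 0, 0))
  set.seed(6)
  d$y <- 1 + d$x1 - d$x2 + rnorm(6, 0, 0.1)
  f <- ols_diagnose(y ~ x1 + x2, d)
  expect_equal(unname(f$vif), c(1, 1))
  expect_equal(unname(f$tolerance), c(1, 1))

  # VIF from auxiliary regressions agrees with car::vif on a collinear design
  set.seed(7)
  dc <- data.frame(x1 = rnorm(30))
  dc$x2 <- dc$x1 + rnorm(30, 0, 0.4)
  dc$y <- 1 + dc$x1 + rnorm(30)
  f2 <- ols_diagnose(y ~ x1 + x2, dc)
  expect_equal(unname(f2$vif), unname(car::vif(lm(y ~ x1 + x2, dc))),
               tolerance = 1e-8)

  # diagnostics ranges
  expect_true(f2$diagnostics$durbin_watson$statistic >= 0 &&
                f2$diagnostics$durbin_watson$statistic <= 4)
  expect_true(f2$diagnostics$white$statistic >= 0)
  expect_true(f2$diagnostics$shapiro_wilk$statistic <= 1)

  # White test falls back when cross-products exhaust df (n = 8, 3 terms)
  set.seed(8)
  d8 <- data.frame(x1 = rnorm(8), x2 = rnorm(8), x3 = rnorm(8))
  d8$y <- 1 + d8$x1 + rnorm(8, 0, 0.2)
  f8 <- ols_diagnose(y ~ x1 + x2 + x3, d8)
  expect_false(f8$diagnostics$white$cross_products)
  expect_true(is.finite(f8$diagnostics$white$p_value))
})

test_that("Durbin-Watson concentrates near 2 for independent residuals", {
  set.seed(51)
  dws <- replicate(500, {
    d <- data.frame(x = rnorm(50))
    d$y <- 1 + d$x + rnorm(50)
    rainweibull:::durbin_watson_stat(residuals(lm(y ~ x, d)))
  })
  expect_gt(mean(dws), 1.8)
  expect_lt(mean(dws), 2.2)
})

test_that("stepwise selection finds true predictors and resists noise", {
  set.seed(61)
  n <- 30
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 2 + 3 * d$x1  # exact in x1, x2 pure noise
  path <- stepwise_select("y", c("x1", "x2"), d)
  expect_identical(path$steps[[1]]$entered, "x1")
  # x2 never significant at the 1% reporting screen
  expect_false(isTRUE(path$significant_at_report["x2"]))
  # R^2 non-decreasing along the path
  r2 <- vapply(path$steps, `[[`, numeric(1), "r_squared")
  expect_true(all(diff(r2) >= -1e-12))

  # all-noise candidates: per-candidate entry rate near alpha_enter
  set.seed(62)
  entered <- replicate(300, {
    d <- data.frame(x1 = rnorm(12), y = rnorm(12))
    length(stepwise_select("y", "x1", d, alpha_enter = 0.15)$selected)
  })
  expect_gt(mean(entered), 0.15 - 2.576 * sqrt(0.15 * 0.85 / 300))
  expect_lt(mean(entered), 0.15 + 2.576 * sqrt(0.15 * 0.85 / 300))

  expect_error(stepwise_select("y", character(0), d), "candidate")
})

test_that("rainfall enters the stepwise path first on a study-like panel", {
  panel <- panel_from_model(noise_sd = 0.05, seed = 13)
  # Tavg weakly collinear with rainfall, ISMP independent
  set.seed(14)
  panel$t_avg <- 18 + 0.0001 * panel$prec_mm + rnorm(8, 0, 0.4)
  panel$ISMP <- runif(8, 5, 6.2)
  path <- stepwise_select("beta_hat", c("prec_mm", "t_avg", "ISMP"), panel)
  expect_identical(path$steps[[1]]$entered, "prec_mm")
  expect_true(path$significant_at_report["prec_mm"])
})

test_that("dummy-variable site test detects only real site effects", {
  # both sites generated from the identical rainfall equation (+ small noise)
  panel <- panel_from_model(noise_sd = 0.05, seed = 15)
  same <- dummy_site_model(panel, "beta_hat", "prec_mm")
  expect_false(same$site_effect)

  # shift one site's intercept by ~10 residual sd: effect must be detected
  shifted <- panel
  shifted$beta_hat[shifted$site_id == "Piratini"] <-
    shifted$beta_hat[shifted$site_id == "Piratini"] + 10 * 0.05
  diff_site <- dummy_site_model(shifted, "beta_hat", "prec_mm")
  expect_true(diff_site$site_effect)

  one_site <- panel[panel$site_id == "Cristal", ]
  expect_error(dummy_site_model(one_site), "two planting sites")
})
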