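test_that("predict_params reproduces the printed linear equations", {
  m <- rainfall_weibull_model()
  # intercepts at Prec -> 0 (evaluated just inside the open lower bound)
  p0 <- predict_params(m, 1e-9)
  expect_equal(unname(p0["shape"]), 5.62235, tolerance = 1e-6)
  expect_equal(unname(p0["scale"]), 4.29692, tolerance = 1e-6)

  p1000 <- predict_params(m, 1000)
  expect_equal(unname(p1000["shape"]), 5.41742)
  expect_equal(unname(p1000["scale"]), 5.35692)

  expect_error(predict_params(m, 30000), "valid range")
  expect_error(predict_params(m, 30000), "shape")
  # upper end of the admissible interval: shape zero near 27435 mm
  expect_equal(m$valid_range[2], 5.62235 / 0.00020493)
})

test_that("predict_params is exactly affine (midpoint property)", {
  m <- rainfall_weibull_model()
  for (pair in list(c(500, 2500), c(1000, 9000), c(123.4, 20000))) {
    a <- predict_params(m, pair[1])
    b <- predict_params(m, pair[2])
    mid <- predict_params(m, mean(pair))
    expect_equal(unname(mid), unname((a + b) / 2), tolerance = 1e-12)
  }
})

test_that("predicted density normalizes and shifts right with rainfall", {
  m <- rainfall_weibull_model()
  for (prec in c(800, 5000, 10500)) {
    expect_equal(integrate(function(x) predicted_pdf(m, prec, x), 0, Inf,
                           rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
    expect_equal(predicted_pdf(m, prec, 0), 0)  # shape > 1 across the range
  }
  mean_at <- function(prec) {
    p <- predict_params(m, prec)
    weibull_moments(p[["shape"]], p[["scale"]])$mean
  }
  expect_gt(mean_at(9000), mean_at(1300))
  # model-implied mean strictly increasing over the sweep
  means <- vapply(seq(100, 20000, by = 100), mean_at, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("scenario simulation covers the level-age grid with valid masses", {
  m <- rainfall_weibull_model()
  s <- simulate_scenarios(m)
  expect_identical(length(s$scenarios), 16L)
  expect_identical(nrow(s$summary), 16L)

  one <- simulate_scenarios(m, annual_levels = 1300, ages = 5, max_dbh = 61)
  pr <- one$scenarios[[1]]$classes$probability
  expect_true(all(pr >= 0))
  # a wide grid captures all mass except the negligible sub-origin tail
  expect_lte(sum(pr), 1)
  expect_equal(sum(pr), 1, tolerance = 1e-4)

  # stochastic ordering: wetter regime -> more large trees at any age
  s2 <- simulate_scenarios(m, annual_levels = c(800, 1500), ages = 7)
  p_big <- vapply(s2$scenarios, function(sc)
    sum(sc$classes$probability[sc$classes$midpoint > 12]), numeric(1))
  expect_gt(p_big[s2$summary$annual_rainfall_mm == 1500],
            p_big[s2$summary$annual_rainfall_mm == 800])
  # first-order dominance over the diameter-class range (the two predicted
  # CDFs cross below ~2.5 cm where both carry only ~1e-3 mass)
  cdf_dry <- predict_params(m, 800 * 7)
  cdf_wet <- predict_params(m, 1500 * 7)
  g <- seq(3, 40, 0.1)
  expect_true(all(pweibull(g, cdf_wet[["shape"]], cdf_wet[["scale"]]) <=
                    pweibull(g, cdf_dry[["shape"]], cdf_dry[["scale"]]) + 1e-12))

  # invalid accumulated rainfall becomes an error entry, run continues
  s3 <- simulate_scenarios(m, annual_levels = c(1300, 5000), ages = c(1, 7))
  errs <- vapply(s3$scenarios, function(sc) !is.null(sc$error), logical(1))
  expect_identical(sum(errs), 1L)  # only 5000 mm/yr x 7 yr exceeds the range
  expect_identical(nrow(s3$summary), 4L)

  expect_error(simulate_scenarios(m, annual_levels = -5), "positive")
})

test_that("predicted-vs-fitted comparison flags only real mismatches", {
  m <- rainfall_weibull_model()
  prec <- 1350 * 5
  p <- predict_params(m, prec)
  same <- rainweibull:::new_fitted_dist("weibull2", c(shape = p[["shape"]],
                                                      scale = p[["scale"]]),
                                        NA_real_, 90L)
  r0 <- compare_predicted_vs_fitted(m, prec, same, n_eff = 90)
  expect_equal(r0$statistic, 0)
  expect_false(r0$significant)

  # a stand generated from the model, then directly fitted: no difference
  d <- stand_design("Cristal", 5, 90, c(3, 1.5), 1350, seed = 77)
  fit <- fit_mle(generate_stand(d, model = m)$dbh_cm, "weibull2")
  r1 <- compare_predicted_vs_fitted(m, prec, fit, n_eff = 90, alpha = 0.01)
  expect_false(r1$significant)

  # +50% scale perturbation must be detected
  off <- same
  off$params["scale"] <- off$params["scale"] * 1.5
  r2 <- compare_predicted_vs_fitted(m, prec, off, n_eff = 90, alpha = 0.01)
  expect_true(r2$significant)
})

test_that("generate -> fit -> compare closes in at least 95% of runs", {
  m <- rainfall_weibull_model()
  set.seed(71)
  ok <- vapply(1:200, function(i) {
    d <- stand_design("S", sample(c(1L, 3L, 5L, 7L), 1), 100, c(3, 1.5),
                      runif(1, 800, 1500), seed = 1000L + i)
    prec <- d$annual_rainfall_mm * d$age_years
    fit <- fit_mle(generate_stand(d, model = m)$dbh_cm, "weibull2")
    !compare_predicted_vs_fitted(m, prec, fit, n_eff = 100, alpha = 0.01)$significant
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("the rainfall model can be re-estimated from an estimator panel", {
  m <- rainfall_weibull_model()
  prec <- c(1200, 1350, 3600, 4050, 6000, 6750, 8400, 9450)
  par <- predict_params(m, prec)
  panel <- data.frame(site_id = rep(c("A", "B"), 4), age_years = rep(c(1, 3, 5, 7), 2),
                      gamma_hat = par[, "shape"], beta_hat = par[, "scale"],
                      prec_mm = prec)
  est <- estimate_rainfall_model(panel)
  expect_equal(est$model$gamma_intercept, 5.62235, tolerance = 1e-8)
  expect_equal(est$model$gamma_slope, -0.00020493, tolerance = 1e-6)
  expect_equal(est$model$beta_intercept, 4.29692, tolerance = 1e-8)
  expect_equal(est$model$beta_slope, 0.00106, tolerance = 1e-6)
  expect_equal(est$beta_fit$r_squared, 1)
})
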