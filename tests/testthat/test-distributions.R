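test_that("diameter-class binning follows the 2 cm / origin 1 convention", {
  one <- bin_diameters(4.9)
  occupied <- one[one$count > 0, ]
  expect_equal(occupied$class_lower, 3)
  expect_equal(occupied$class_upper, 5)
  expect_equal(occupied$midpoint, 4)

  low <- bin_diameters(c(1.27, 6, 9))
  expect_equal(low$count[low$class_lower == 1], 1L)

  set.seed(2)
  x <- rweibull(500, 4, 9) + 1
  tab <- bin_diameters(x)
  expect_equal(sum(tab$rel_freq), 1, tolerance = 1e-9)
  expect_identical(sum(tab$count), 500L)
  # contiguity and fixed width
  expect_equal(tab$class_lower[-1], tab$class_upper[-nrow(tab)])
  expect_true(all(tab$class_upper - tab$class_lower == 2))
  expect_equal(tab$class_lower[1], 1)
  # a value exactly on the top break still gets a class ([lower, upper))
  edge <- bin_diameters(c(2, 5))
  expect_identical(sum(edge$count), 2L)
  expect_equal(max(edge$class_upper), 7)

  expect_error(bin_diameters(numeric(0)), "non-empty")
  expect_error(bin_diameters(c(0.5, 3)), "below the class origin")
})

test_that("weibull2_pdf matches its closed form and normalizes", {
  # x = scale: density (shape/scale) e^-1
  expect_equal(weibull2_pdf(14.10406, 4.085136, 14.10406),
               (4.085136 / 14.10406) * exp(-1))
  expect_equal(weibull2_pdf(0, 4.085136, 14.10406), 0)
  expect_equal(weibull2_pdf(seq(0.5, 25, 0.5), 3.454949, 11.455),
               dweibull(seq(0.5, 25, 0.5), 3.454949, 11.455))
  q <- integrate(weibull2_pdf, 0, 60, shape = 4.085136, scale = 14.10406,
                 rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(weibull2_pdf(-1, 4, 14), "non-negative")
  expect_error(weibull2_pdf(1, -4, 14), "positive")
})

test_that("every candidate pdf integrates to 1 over its support", {
  set.seed(7)
  x <- rweibull(400, 4, 9) + 0.5
  for (fam in c("normal", "lognormal", "gamma2", "weibull2", "weibull3")) {
    f <- fit_mle(x, fam)
    lo <- if (fam == "normal") -Inf else if (fam == "weibull3")
      f$params[["location"]] else 0
    expect_equal(integrate(function(v) dist_pdf(f, v), lo, Inf,
                           rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6, label = fam)
  }
})

test_that("normal MLE has its closed form (mean, divide-by-n sd)", {
  set.seed(3)
  x <- rnorm(50, 10, 2)
  f <- fit_mle(x, "normal")
  expect_equal(unname(f$params["mean"]), mean(x))
  expect_equal(unname(f$params["sd"]), sqrt(mean((x - mean(x))^2)))
  expect_equal(f$loglik, sum(dnorm(x, f$params["mean"], f$params["sd"], log = TRUE)))
})

test_that("MLE recovers generating parameters within 2% at n = 1e5", {
  gens <- list(
    normal = function(n) rnorm(n, 10, 2),
    lognormal = function(n) rlnorm(n, 2, 0.3),
    gamma2 = function(n) rgamma(n, shape = 5, scale = 2),
    weibull2 = function(n) rweibull(n, 4.085402, 8.976419)
  )
  truth <- list(normal = c(mean = 10, sd = 2),
                lognormal = c(meanlog = 2, sdlog = 0.3),
                gamma2 = c(shape = 5, scale = 2),
                weibull2 = c(shape = 4.085402, scale = 8.976419))
  for (fam in names(gens)) {
    set.seed(101)
    f <- fit_mle(gens[[fam]](1e5), fam)
    for (p in names(truth[[fam]])) {
      expect_lt(abs(f$params[[p]] - truth[[fam]][[p]]) / abs(truth[[fam]][[p]]),
                0.02, label = paste(fam, p))
    }
  }
})

test_that("three-parameter Weibull profile fit recovers a shifted sample", {
  set.seed(11)
  x <- 3 + rweibull(5e4, 3.5, 8)
  f <- fit_mle(x, "weibull3")
  expect_lt(f$params[["location"]], min(x))
  expect_lt(abs(f$params[["location"]] - 3), 0.25)
  expect_lt(abs(f$params[["shape"]] - 3.5) / 3.5, 0.05)
  expect_lt(abs(f$params[["scale"]] - 8) / 8, 0.05)
})

test_that("fitted parameters are a local maximum of the log-likelihood", {
  set.seed(5)
  x <- rweibull(2000, 4, 9)
  for (fam in c("weibull2", "gamma2", "lognormal", "normal")) {
    f <- fit_mle(x, fam)
    for (j in seq_along(f$params)) {
      for (mult in c(0.99, 1.01)) {
        g <- f
        g$params[j] <- g$params[j] * mult
        expect_lte(dist_loglik(g, x), f$loglik + 1e-8,
                   label = sprintf("%s param %d x%.2f", fam, j, mult))
      }
    }
  }
})

test_that("fit_mle rejects degenerate and invalid samples", {
  expect_error(fit_mle(rep(5, 20), "weibull2"), "degenerate")
  expect_error(fit_mle(c(rweibull(20, 4, 9), NA), "weibull2"), "non-finite")
  expect_error(fit_mle(rweibull(5, 4, 9), "weibull2"), "at least 10")
  expect_error(fit_mle(c(-1, rweibull(19, 4, 9)), "lognormal"), "positive")
})

test_that("weibull_moments matches closed forms and Monte-Carlo", {
  m <- weibull_moments(1, 5)
  expect_equal(m$mean, 5)       # exponential special case
  expect_equal(m$mode, 0)
  expect_equal(m$variance, 25)

  # moments reproduce the reference per-age means
  m1 <- weibull_moments(4.115712, 5.606776)
  expect_equal(m1$mean, 5.09, tolerance = 0.001)
  m7 <- weibull_moments(4.085136, 14.10406)
  expect_equal(m7$mean, 12.79, tolerance = 0.0015)

  set.seed(12)
  x <- rweibull(1e6, 3.454949, 11.455)
  mm <- weibull_moments(3.454949, 11.455)
  expect_lt(abs(mean(x) - mm$mean), 3 * sqrt(mm$variance / 1e6))
  expect_equal(median(x), mm$median, tolerance = 0.02)

  expect_error(weibull_moments(-1, 5), "positive")
})
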