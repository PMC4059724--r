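# Brute-force oracles for the EDF goodness-of-fit statistics: naive loops
# over their defining sums, kept independent of the package's vectorized
# implementations.

oracle_ks <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  d <- 0
  for (i in seq_len(n)) {
    d <- max(d, i / n - cdf(x[i]), cdf(x[i]) - (i - 1) / n)
  }
  d
}

oracle_ad <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    s <- s + (2 * i - 1) * (log(cdf(x[i])) + log(1 - cdf(x[n + 1 - i])))
  }
  -n - s / n
}

oracle_cvm <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  s <- 1 / (12 * n)
  for (i in seq_len(n)) {
    s <- s + (cdf(x[i]) - (2 * i - 1) / (2 * n))^2
  }
  s
}

# textbook closed-form simple OLS on (x, y): slope/intercept via covariances
oracle_ols_simple <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b1 * mean(x), slope = b1)
}

ref_coefs <- wattle_age_coefficients()

ref_fit <- function(age) {
  r <- ref_coefs[ref_coefs$age_years == age, ]
  rainweibull:::new_fitted_dist("weibull2",
                                c(shape = r$shape, scale = r$scale),
                                NA_real_, r$n_trees)
}
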