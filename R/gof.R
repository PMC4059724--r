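new_gof_result <- function(statistic_name, statistic, alpha, significant,
                           p_value = NA_real_, note = NULL) {
  structure(list(statistic_name = statistic_name,
                 statistic = unname(statistic),
                 alpha = alpha,
                 significant = significant,
                 p_value = unname(p_value),
                 note = note),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("%s = %.5f, alpha = %g: %s", x$statistic_name, x$statistic,
              x$alpha, if (isTRUE(x$significant)) "significant" else "not significant"))
  if (is.finite(x$p_value)) cat(sprintf(" (p = %.4f)", x$p_value))
  cat("\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# survival function of the Kolmogorov distribution: P(sqrt(n) D > t)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

sorted_cdf_values <- function(dbh, fit, clamp = FALSE) {
  u <- dist_cdf(fit, sort(dbh))
  if (any(!is.finite(u))) stop("fitted CDF undefined at a sample point")
  if (clamp) {
    if (any(u <= 0 | u >= 1)) {
      warning("CDF values numerically 0 or 1 clamped to [1e-12, 1 - 1e-12]")
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    }
  }
  u
}

#' One-sample Kolmogorov-Smirnov test against a fitted distribution
#'
#' Computes \eqn{D = \max_i \max(i/n - F(x_{(i)}),\ F(x_{(i)}) - (i-1)/n)}.
#' In `asymptotic` mode the decision uses the known-parameter Kolmogorov
#' distribution of \eqn{\sqrt{n} D} — the convention of classical
#' distribution-fitting software even when parameters were estimated from
#' the same sample, which makes the test conservative in that case.
#' `bootstrap` mode calibrates the null properly: `B` parametric resamples
#' from `fit` are each refitted (same family) and their `D*` form the
#' reference distribution.
#'
#' @param dbh Sample of diameters (cm), `n >= 5`.
#' @param fit A `fitted_dist`.
#' @param alpha Significance level (default 0.05).
#' @param mode `"asymptotic"` or `"bootstrap"`.
#' @param B Bootstrap replicates (default 999).
#' @return A `gof_result` with the statistic, p-value and decision.
#' @export
ks_one_sample <- function(dbh, fit, alpha = 0.05,
                          mode = c("asymptotic", "bootstrap"), B = 999) {
  mode <- match.arg(mode)
  n <- length(dbh)
  if (n < 5) stop("need n >= 5")
  D <- ks_stat(dbh, fit)
  if (mode == "asymptotic") {
    p <- kolmogorov_sf(sqrt(n) * D)
  } else {
    Dstar <- replicate(B, {
      xb <- dist_rng(fit, n)
      ks_stat(xb, fit_mle(xb, fit$family))
    })
    p <- (1 + sum(Dstar >= D)) / (B + 1)
  }
  new_gof_result("KS", D, alpha, p <= alpha, p)
}

ks_stat <- function(dbh, fit) {
  n <- length(dbh)
  u <- sorted_cdf_values(dbh, fit)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' Anderson-Darling test against a fitted distribution
#'
#' Computes
#' \eqn{A^2 = -n - \frac{1}{n}\sum (2i-1)[\ln F(x_{(i)}) + \ln(1-F(x_{(n+1-i)}))]},
#' the tail-weighted EDF statistic. CDF values numerically at 0 or 1 are
#' clamped to `[1e-12, 1-1e-12]` with a warning. The decision is calibrated
#' by parametric bootstrap (refit on each of `B` resamples), which accounts
#' for parameter estimation.
#'
#' @inheritParams ks_one_sample
#' @return A `gof_result`.
#' @export
ad_statistic <- function(dbh, fit, alpha = 0.05, B = 999,
                         mode = c("bootstrap", "statistic_only")) {
  mode <- match.arg(mode)
  A2 <- ad_stat(dbh, fit)
  if (mode == "statistic_only") {
    return(new_gof_result("AD", A2, alpha, NA, NA_real_,
                          note = "statistic only; no calibration requested"))
  }
  n <- length(dbh)
  A2star <- replicate(B, {
    xb <- dist_rng(fit, n)
    ad_stat(xb, fit_mle(xb, fit$family))
  })
  p <- (1 + sum(A2star >= A2)) / (B + 1)
  new_gof_result("AD", A2, alpha, p <= alpha, p)
}

ad_stat <- function(dbh, fit) {
  n <- length(dbh)
  u <- sorted_cdf_values(dbh, fit, clamp = TRUE)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' Cramer-von Mises test against a fitted distribution
#'
#' Computes \eqn{W^2 = \frac{1}{12n} + \sum_i (F(x_{(i)}) - \frac{2i-1}{2n})^2},
#' the quadratic EDF statistic, with the same parametric-bootstrap
#' calibration as [ad_statistic()].
#'
#' @inheritParams ad_statistic
#' @return A `gof_result`.
#' @export
cvm_statistic <- function(dbh, fit, alpha = 0.05, B = 999,
                          mode = c("bootstrap", "statistic_only")) {
  mode <- match.arg(mode)
  W2 <- cvm_stat(dbh, fit)
  if (mode == "statistic_only") {
    return(new_gof_result("CvM", W2, alpha, NA, NA_real_,
                          note = "statistic only; no calibration requested"))
  }
  n <- length(dbh)
  W2star <- replicate(B, {
    xb <- dist_rng(fit, n)
    cvm_stat(xb, fit_mle(xb, fit$family))
  })
  p <- (1 + sum(W2star >= W2)) / (B + 1)
  new_gof_result("CvM", W2, alpha, p <= alpha, p)
}

cvm_stat <- function(dbh, fit) {
  n <- length(dbh)
  u <- sorted_cdf_values(dbh, fit, clamp = TRUE)
  i <- seq_len(n)
  1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
}

#' Two-sample Kolmogorov-Smirnov test between two distribution curves
#'
#' Compares two CDF-like curves (fitted distributions, rainfall-model
#' predictions, or plain functions) by the supremum gap over a fine grid,
#' with the large-sample critical value
#' \eqn{c(\alpha)\sqrt{(n_a + n_b)/(n_a n_b)}},
#' \eqn{c(\alpha) = \sqrt{-\ln(\alpha/2)/2}}. The effective sample sizes are
#' those of the samples behind each curve; when fitted curves of measured
#' stands are compared, the per-stand tree counts play that role.
#'
#' @param curve_a,curve_b `fitted_dist` objects or functions `q -> F(q)`.
#' @param n_eff_a,n_eff_b Effective sample sizes behind each curve (> 0).
#' @param alpha Significance level (default 0.01).
#' @param grid Evaluation grid (cm). Default: 0.01 cm steps over
#'   `[0, grid_max]`.
#' @param grid_max Upper end of the default grid; defaults to 1.5 times the
#'   larger scale-like spread of the two curves (45 cm fallback for plain
#'   functions).
#' @return A `gof_result` (`statistic_name = "KS2"`) whose `p_value` is the
#'   asymptotic two-sample approximation.
#' @export
ks_two_sample <- function(curve_a, curve_b, n_eff_a, n_eff_b, alpha = 0.01,
                          grid = NULL, grid_max = NULL) {
  check_positive(n_eff_a = n_eff_a, n_eff_b = n_eff_b)
  Fa <- as_cdf_function(curve_a)
  Fb <- as_cdf_function(curve_b)
  if (is.null(grid)) {
    if (is.null(grid_max)) {
      grid_max <- 1.5 * max(curve_spread(curve_a), curve_spread(curve_b))
    }
    grid <- seq(0, grid_max, by = 0.01)
  }
  if (length(grid) == 0) stop("empty evaluation grid")
  D <- max(abs(Fa(grid) - Fb(grid)))
  crit <- sqrt(-log(alpha / 2) / 2) * sqrt((n_eff_a + n_eff_b) / (n_eff_a * n_eff_b))
  n_e <- n_eff_a * n_eff_b / (n_eff_a + n_eff_b)
  p <- kolmogorov_sf(sqrt(n_e) * D)
  new_gof_result("KS2", D, alpha, D > crit, p,
                 note = sprintf("critical value %.5f at alpha = %g (n_eff %g, %g)",
                                crit, alpha, n_eff_a, n_eff_b))
}

as_cdf_function <- function(curve) {
  if (inherits(curve, "fitted_dist")) return(function(q) dist_cdf(curve, q))
  if (is.function(curve)) return(curve)
  stop("curve must be a fitted_dist or a CDF function")
}

curve_spread <- function(curve) {
  if (inherits(curve, "fitted_dist")) {
    q <- dist_quantile(curve, 0.999)
    if (is.finite(q)) return(q)
  }
  30
}

#' Select the preferred adequate distribution family
#'
#' Given one goodness-of-fit result per candidate family, keeps the families
#' whose fit was not rejected and returns the preferred one. The default
#' preference puts the two-parameter Weibull first: its estimators are the
#' ones related to environmental covariates downstream, so it wins whenever
#' it is adequate.
#'
#' @param results Named list of `gof_result`s, names = families.
#' @param preference Character vector ordering the families.
#' @return List with `family` (or `NA` when nothing fits), `adequate`
#'   logical, and `candidates` (all non-rejected families).
#' @export
select_distribution <- function(results,
                                preference = c("weibull2", "weibull3", "gamma2",
                                               "normal", "lognormal")) {
  if (length(results) == 0) stop("no goodness-of-fit results supplied")
  stopifnot(!is.null(names(results)))
  keep <- names(results)[!vapply(results, function(r) isTRUE(r$significant),
                                 logical(1))]
  if (length(keep) == 0) {
    return(list(family = NA_character_, adequate = FALSE, candidates = character(0)))
  }
  ordered <- c(intersect(preference, keep), setdiff(keep, preference))
  list(family = ordered[1], adequate = TRUE, candidates = keep)
}

#' Goodness-of-fit matrix across families and stand ages
#'
#' Fits every candidate family to every age's pooled sample and runs the
#' one-sample KS test, producing the families-by-ages decision matrix used
#' to pick the working distribution.
#'
#' @param trees Tree table (`site_id`, `plot_id`, `age_years`, `dbh_cm`).
#' @param families Candidate families.
#' @param alpha KS significance level.
#' @param mode Passed to [ks_one_sample()].
#' @return List with `stats` (data.frame of KS statistics, rows = families),
#'   `significant` (logical matrix of the same shape) and `fits` (nested
#'   list `fits[[age]][[family]]`).
#' @export
gof_matrix <- function(trees, families = supported_families, alpha = 0.05,
                       mode = "asymptotic") {
  ages <- sort(unique(trees$age_years))
  fits <- list()
  stat <- matrix(NA_real_, length(families), length(ages),
                 dimnames = list(families, paste0("age_", ages)))
  sig <- stat == 1
  for (j in seq_along(ages)) {
    x <- trees$dbh_cm[trees$age_years == ages[j]]
    fits[[as.character(ages[j])]] <- list()
    for (fam in families) {
      f <- fit_mle(x, fam)
      r <- ks_one_sample(x, f, alpha = alpha, mode = mode)
      fits[[as.character(ages[j])]][[fam]] <- f
      stat[fam, j] <- r$statistic
      sig[fam, j] <- r$significant
    }
  }
  list(stats = as.data.frame(stat), significant = sig, fits = fits)
}
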