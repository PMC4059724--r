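#' Per-stand Weibull estimator panel
#'
#' Fits the two-parameter Weibull to every stand (site by age) of a tree
#' table and joins the environmental covariates, producing the panel on
#' which correlations, stepwise selection and the site-effect test run.
#'
#' @param trees Tree table (`site_id`, `age_years`, `dbh_cm`).
#' @param env Environmental table, one row per stand (`site_id`,
#'   `age_years`, covariates).
#' @return `data.frame`: one row per stand with `gamma_hat` (shape),
#'   `beta_hat` (scale) and the joined covariates.
#' @export
estimator_panel <- function(trees, env) {
  key <- unique(trees[c("site_id", "age_years")])
  key <- key[order(key$site_id, key$age_years), , drop = FALSE]
  fits <- mapply(function(site, age) {
    fit_mle(trees$dbh_cm[trees$site_id == site & trees$age_years == age],
            "weibull2")$params
  }, key$site_id, key$age_years, SIMPLIFY = FALSE)
  key$gamma_hat <- vapply(fits, `[[`, numeric(1), "shape")
  key$beta_hat <- vapply(fits, `[[`, numeric(1), "scale")
  out <- merge(key, env, by = c("site_id", "age_years"), sort = FALSE)
  if (anyNA(out$gamma_hat) || anyNA(out$beta_hat)) stop("missing estimator values")
  out[order(out$site_id, out$age_years), , drop = FALSE]
}

#' Correlate Weibull estimators with environmental covariates
#'
#' Pearson product-moment correlations of the per-stand shape (`gamma_hat`)
#' and scale (`beta_hat`) estimators with every covariate, sorted ascending
#' by the correlation with the shape parameter. A covariate with zero
#' variance gets `NA` correlations rather than an error.
#'
#' @param panel An [estimator_panel()] result.
#' @param covariates Covariate columns to use; default: every numeric column
#'   other than the estimators and `age_years`.
#' @return `data.frame` with `variable`, `r_gamma`, `r_beta`.
#' @export
correlate_estimators <- function(panel, covariates = NULL) {
  if (nrow(panel) < 3) stop("need at least 3 stands")
  if (is.null(covariates)) {
    num <- vapply(panel, is.numeric, logical(1))
    covariates <- setdiff(names(panel)[num],
                          c("gamma_hat", "beta_hat", "age_years"))
  }
  safe_cor <- function(x, y) {
    if (!all(is.finite(x))) stop("non-finite covariate values")
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  out <- data.frame(
    variable = covariates,
    r_gamma = vapply(covariates, function(v) safe_cor(panel[[v]], panel$gamma_hat),
                     numeric(1)),
    r_beta = vapply(covariates, function(v) safe_cor(panel[[v]], panel$beta_hat),
                    numeric(1))
  )
  out[order(out$r_gamma), , drop = FALSE]
}

durbin_watson_stat <- function(e) {
  sum(diff(e)^2) / sum(e^2)
}

# White heteroscedasticity test: n R^2 of the auxiliary regression of squared
# residuals on regressors, their squares and cross-products; falls back to the
# no-cross-product variant when the auxiliary design exhausts the degrees of
# freedom (routine at n = 8).
white_test <- function(model) {
  e2 <- stats::residuals(model)^2
  X <- stats::model.matrix(model)
  Z <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  n <- length(e2)
  build <- function(cross) {
    out <- Z
    for (j in seq_len(ncol(Z))) {
      out <- cbind(out, Z[, j]^2)
      if (cross && j < ncol(Z)) {
        for (k in (j + 1):ncol(Z)) out <- cbind(out, Z[, j] * Z[, k])
      }
    }
    out[, !duplicated(t(out)), drop = FALSE]
  }
  aux <- build(cross = TRUE)
  used_cross <- TRUE
  if (n - qr(cbind(1, aux))$rank <= 0) {
    aux <- build(cross = FALSE)
    used_cross <- FALSE
    if (n - qr(cbind(1, aux))$rank <= 0) {
      aux <- Z  # last resort: Breusch-Pagan style levels only
    }
  }
  fit <- stats::lm(e2 ~ aux)
  df <- qr(stats::model.matrix(fit))$rank - 1
  stat <- n * summary(fit)$r.squared
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       cross_products = used_cross)
}

vif_from_design <- function(X) {
  # X: model matrix without intercept column
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Ordinary least squares with a regression-diagnostic battery
#'
#' Fits a linear model and computes the diagnostics used to vet
#' environment-driven parameter models: Durbin-Watson (residual
#' independence), White (homoscedasticity; cross-product auxiliary
#' regression, with an automatic fallback to the no-cross-product variant
#' when the auxiliary design would exhaust the degrees of freedom),
#' Shapiro-Wilk (residual normality), and per-term variance inflation
#' factors with their reciprocal tolerances.
#'
#' @param formula Model formula with intercept.
#' @param data Data frame; must have more rows than model columns.
#' @return Object of class `regression_fit`: `model` (the `lm`),
#'   `coefficients` (table with estimates, SE, t, p), `r_squared`,
#'   `diagnostics` (list `durbin_watson`, `white`, `shapiro_wilk`, each with
#'   statistic and p-value), `vif`, `tolerance`.
#' @examples
#' d <- data.frame(x = 1:8, y = 4.29692 + 0.00106 * (1:8) * 1000)
#' ols_diagnose(y ~ x, d)$coefficients
#' @export
ols_diagnose <- function(formula, data) {
  model <- stats::lm(formula, data = data)
  X <- stats::model.matrix(model)
  if (nrow(X) <= ncol(X)) stop("need more observations than model columns")
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[is.na(stats::coef(model))]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  sm <- summary(model)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std_error", "t_value", "p_value")
  e <- stats::residuals(model)
  dw <- lmtest::dwtest(model)
  wt <- white_test(model)
  sw <- if (length(e) >= 3 && stats::sd(e) > 0) stats::shapiro.test(e) else
    list(statistic = NA_real_, p.value = NA_real_)
  Xn <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vif <- vif_from_design(Xn)
  structure(list(
    model = model,
    response = all.vars(formula)[1],
    coefficients = co,
    r_squared = sm$r.squared,
    diagnostics = list(
      durbin_watson = list(statistic = unname(dw$statistic),
                           p_value = unname(dw$p.value)),
      white = wt,
      shapiro_wilk = list(statistic = unname(sw$statistic),
                          p_value = unname(sw$p.value))
    ),
    vif = vif,
    tolerance = 1 / vif
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit for %s  (R^2 = %.4f)\n", x$response, x$r_squared))
  print(round(x$coefficients, 6))
  d <- x$diagnostics
  cat(sprintf("Durbin-Watson %.3f (p %.3f) | White %.3f (p %.3f%s) | Shapiro-Wilk %.3f (p %.3f)\n",
              d$durbin_watson$statistic, d$durbin_watson$p_value,
              d$white$statistic, d$white$p_value,
              if (d$white$cross_products) "" else ", no cross-products",
              d$shapiro_wilk$statistic, d$shapiro_wilk$p_value))
  if (length(x$vif)) {
    cat("VIF:", paste(sprintf("%s %.2f", names(x$vif), x$vif), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Forward stepwise selection with partial-F entry and removal
#'
#' Forward selection with replacement: at each step the candidate whose
#' partial F (equivalently squared t) is most significant enters if its
#' p-value is below `alpha_enter`; after each entry, any included variable
#' whose partial p-value rose above `alpha_stay` is removed. Each step
#' records the refitted equation and its R-squared. Final-model terms are
#' additionally flagged at the stricter `report_alpha` screen used when
#' reporting which coefficients survive.
#'
#' @param response Response column name.
#' @param candidates Candidate predictor column names.
#' @param data Data frame.
#' @param alpha_enter,alpha_stay Entry and stay thresholds (default 0.15).
#' @param report_alpha Reporting screen for the final model (default 0.01).
#' @return Object of class `stepwise_path`: `steps` (list per step:
#'   `entered`, `removed`, `coefficients`, `r_squared`, `p_values`),
#'   `selected` (final variables), `final` (the final [ols_diagnose()] fit,
#'   or `NULL` for an empty path) and `significant_at_report` (logical per
#'   final term).
#' @export
stepwise_select <- function(response, candidates, data,
                            alpha_enter = 0.15, alpha_stay = 0.15,
                            report_alpha = 0.01) {
  if (length(candidates) == 0) stop("need at least one candidate")
  if (nrow(data) <= 2) stop("need more than 2 rows")
  current <- character(0)
  steps <- list()
  fit_formula <- function(vars) {
    f <- stats::reformulate(if (length(vars)) vars else "1", response)
    stats::lm(f, data = data)
  }
  repeat {
    remaining <- setdiff(candidates, current)
    if (length(remaining) == 0) break
    # entry: best partial p among remaining, must beat alpha_enter
    pvals <- vapply(remaining, function(v) {
      m <- fit_formula(c(current, v))
      if (nrow(data) <= length(current) + 2) return(NA_real_)
      co <- summary(m)$coefficients
      if (!v %in% rownames(co)) return(NA_real_)
      co[v, 4]
    }, numeric(1))
    pvals <- pvals[is.finite(pvals)]
    if (length(pvals) == 0 || min(pvals) > alpha_enter) break
    entered <- names(pvals)[which.min(pvals)]
    current <- c(current, entered)
    # removal pass
    removed <- character(0)
    repeat {
      m <- fit_formula(current)
      co <- summary(m)$coefficients
      terms_p <- co[setdiff(rownames(co), "(Intercept)"), 4]
      worst <- which.max(terms_p)
      if (length(terms_p) == 0 || terms_p[worst] <= alpha_stay) break
      gone <- names(terms_p)[worst]
      if (gone == entered) break  # never remove what just entered
      current <- setdiff(current, gone)
      removed <- c(removed, gone)
    }
    m <- fit_formula(current)
    sm <- summary(m)
    steps[[length(steps) + 1]] <- list(
      entered = entered, removed = removed,
      variables = current,
      coefficients = stats::coef(m),
      r_squared = sm$r.squared,
      p_values = sm$coefficients[, 4]
    )
  }
  final <- if (length(current)) {
    ols_diagnose(stats::reformulate(current, response), data)
  }
  sig <- if (!is.null(final)) {
    p <- final$coefficients$p_value
    stats::setNames(p <= report_alpha, rownames(final$coefficients))
  } else logical(0)
  structure(list(steps = steps, selected = current, final = final,
                 significant_at_report = sig, report_alpha = report_alpha),
            class = "stepwise_path")
}

#' @export
print.stepwise_path <- function(x, ...) {
  if (length(x$steps) == 0) {
    cat("Stepwise path: empty (no candidate passed the entry threshold)\n")
    return(invisible(x))
  }
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("Step %d: + %s%s  R^2 = %.4f\n", i, s$entered,
                if (length(s$removed)) paste0(" (- ", paste(s$removed, collapse = ", "), ")") else "",
                s$r_squared))
  }
  cat("Selected:", paste(x$selected, collapse = " + "), "\n")
  cat(sprintf("Terms significant at %g%%: %s\n", 100 * x$report_alpha,
              paste(names(x$significant_at_report)[x$significant_at_report],
                    collapse = ", ")))
  invisible(x)
}

#' Dummy-variable test for a planting-site effect
#'
#' Fits `response = b0 + b1 D + b2 x + b3 D x` where `D` is the 0/1 site
#' indicator, and tests the site terms jointly (`b1 = b3 = 0`) by the extra
#' sum-of-squares F test against the site-free model `response = b0 + b2 x`.
#' A non-significant decision means one pooled equation serves both sites.
#'
#' @param panel An [estimator_panel()] with exactly two sites.
#' @param response Response column (`"beta_hat"` or `"gamma_hat"`).
#' @param covariate Covariate column selected by the stepwise stage (e.g.
#'   `"prec_mm"`).
#' @param alpha Significance level of the joint test (default 0.05).
#' @return List: `fit` (the interaction [ols_diagnose()]), `f_statistic`,
#'   `p_value`, `site_effect` (logical), `reference_site`.
#' @export
dummy_site_model <- function(panel, response = "beta_hat", covariate = "prec_mm",
                             alpha = 0.05) {
  sites <- sort(unique(panel$site_id))
  if (length(sites) != 2) stop("need exactly two planting sites, got ", length(sites))
  d <- data.frame(y = panel[[response]],
                  D = as.numeric(panel$site_id == sites[2]),
                  x = panel[[covariate]])
  if (stats::sd(d$D) == 0) stop("site indicator is constant")
  full <- stats::lm(y ~ D + x + D:x, data = d)
  reduced <- stats::lm(y ~ x, data = d)
  a <- stats::anova(reduced, full)
  fit <- ols_diagnose(y ~ D + x + D:x, d)
  list(fit = fit,
       f_statistic = a$F[2],
       p_value = a$`Pr(>F)`[2],
       site_effect = a$`Pr(>F)`[2] <= alpha,
       reference_site = sites[1])
}
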