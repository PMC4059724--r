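tree_columns <- c("site_id", "plot_id", "age_years", "dbh_cm")

#' Read and validate a tree table
#'
#' Reads a comma-separated tree table (UTF-8, "." decimal, mandatory header
#' `site_id, plot_id, age_years, dbh_cm`) and validates every row: `dbh_cm`
#' must be numeric and strictly positive. Validation errors cite the file
#' line (header = line 1).
#'
#' @param path CSV file path.
#' @return `data.frame` of validated tree records (possibly 0 rows, with a
#'   warning).
#' @export
read_tree_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(tree_columns, names(raw))
  if (length(missing)) {
    stop("tree table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    warning("tree table ", path, " has a header but no rows")
    return(data.frame(site_id = character(), plot_id = character(),
                      age_years = integer(), dbh_cm = numeric()))
  }
  dbh <- suppressWarnings(as.numeric(raw$dbh_cm))
  bad <- which(!is.finite(dbh) | dbh <= 0)
  if (length(bad)) {
    stop(sprintf("invalid dbh_cm '%s' on line %d of %s (must be a positive number)",
                 raw$dbh_cm[bad[1]], bad[1] + 1L, path))
  }
  age <- suppressWarnings(as.integer(raw$age_years))
  bad <- which(is.na(age) | age <= 0)
  if (length(bad)) {
    stop(sprintf("invalid age_years '%s' on line %d of %s",
                 raw$age_years[bad[1]], bad[1] + 1L, path))
  }
  data.frame(site_id = raw$site_id, plot_id = raw$plot_id,
             age_years = age, dbh_cm = dbh)
}

#' Write a tree or environment table as CSV
#'
#' Plain CSV: comma separator, "." decimal, header row, no row names, full
#' double precision (round-trips through [read_tree_table()] losslessly).
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-stand environmental table
#'
#' @param path CSV with `site_id`, `age_years` and numeric covariates.
#' @return `data.frame` of class `env_table`.
#' @export
read_env_table <- function(path) {
  env <- utils::read.csv(path)
  need <- c("site_id", "age_years", "prec_mm")
  missing <- setdiff(need, names(env))
  if (length(missing)) {
    stop("environment table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(env$prec_mm < 0)) stop("prec_mm must be non-negative")
  class(env) <- c("env_table", "data.frame")
  env
}

#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration driving
#' [run_pipeline()]: input paths or a synthetic design block, the
#' diameter-class convention, candidate families, significance levels,
#' stepwise thresholds, scenario grid and the master seed.
#'
#' @param tree_csv,env_csv Input CSVs; when `NULL` the synthetic study is
#'   generated instead.
#' @param class_width,origin Diameter-class convention (cm).
#' @param families Candidate distribution families.
#' @param gof_alpha One-sample KS level (default 0.05).
#' @param curve_alpha Curve-comparison KS level (default 0.01).
#' @param gof_mode `"asymptotic"` or `"bootstrap"`.
#' @param confirm_B Bootstrap replicates for the AD/CvM confirmation of the
#'   selected family.
#' @param alpha_enter,alpha_stay,report_alpha Stepwise thresholds.
#' @param scenario_levels,scenario_ages Rainfall scenario grid.
#' @param seed Master seed; every stochastic stage derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tree_csv = NULL, env_csv = NULL,
                            class_width = 2, origin = 1,
                            families = supported_families,
                            gof_alpha = 0.05, curve_alpha = 0.01,
                            gof_mode = "asymptotic", confirm_B = 199,
                            alpha_enter = 0.15, alpha_stay = 0.15,
                            report_alpha = 0.01,
                            scenario_levels = c(800, 1100, 1300, 1500),
                            scenario_ages = c(1, 3, 5, 7),
                            seed = 20140616L) {
  stopifnot(gof_alpha > 0, gof_alpha < 1, curve_alpha > 0, curve_alpha < 1,
            class_width > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
  invisible(NULL)
}

#' Run the full diameter-distribution analysis pipeline
#'
#' Orchestrates every stage in order: load or generate the study; fit the
#' candidate families per age and build the KS decision matrix; select the
#' working family (AD/CvM bootstrap confirmation on the selection); shape
#' statistics per age; per-stand estimator panel; covariate correlations;
#' stepwise models for shape and scale; dummy-variable site-effect test;
#' re-estimated rainfall model with predicted-vs-fitted curve comparison per
#' stand; rainfall scenario simulation. Every table is written as CSV under
#' `out_dir` and listed in a `MANIFEST` with row counts; if a stage fails
#' the run halts and the manifest records the incomplete stage. If no
#' family is adequate, the Weibull-dependent stages are skipped and the
#' manifest says so.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage boundaries via `message()`.
#' @return List with every stage result (invisibly): `trees`, `env`, `gof`,
#'   `selection`, `confirmation`, `shape`, `panel`, `correlations`,
#'   `stepwise_beta`, `stepwise_gamma`, `dummy`, `rainfall_model`,
#'   `comparison`, `scenarios`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("rainweibull_"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write_table_csv(x, p)
    manifest[[name]] <<- nrow(x)
    log_stage(verbose, "wrote %s (%d rows)", p, nrow(x))
  }
  stage <- "load_data"
  result <- try({
    if (!is.null(config$tree_csv)) {
      trees <- read_tree_table(config$tree_csv)
      env <- if (!is.null(config$env_csv)) read_env_table(config$env_csv)
    } else {
      log_stage(verbose, "generating synthetic study (seed %d)", config$seed)
      study <- generate_study(wattle_study_design(seed = config$seed))
      trees <- study$trees; env <- study$env
    }
    emit(trees, "trees")
    if (!is.null(env)) emit(as.data.frame(env), "env")

    stage <- "gof_matrix"
    gof <- gof_matrix(trees, config$families, config$gof_alpha, config$gof_mode)
    gof_out <- cbind(family = rownames(gof$stats), gof$stats,
                     as.data.frame(stats::setNames(
                       lapply(seq_len(ncol(gof$significant)),
                              function(j) ifelse(gof$significant[, j], "*", "ns")),
                       paste0("flag_", colnames(gof$significant)))))
    emit(gof_out, "gof_matrix")

    stage <- "selection"
    ages <- sort(unique(trees$age_years))
    per_age_sel <- lapply(as.character(ages), function(a) {
      res <- lapply(rownames(gof$stats), function(fam) {
        new_gof_result("KS", gof$stats[fam, paste0("age_", a)], config$gof_alpha,
                       gof$significant[fam, paste0("age_", a)])
      })
      select_distribution(stats::setNames(res, rownames(gof$stats)))
    })
    adequate_all <- all(vapply(per_age_sel, `[[`, logical(1), "adequate"))
    selected <- if (adequate_all) {
      fams <- vapply(per_age_sel, `[[`, character(1), "family")
      # the family adequate at every age, by preference order
      common <- Reduce(intersect, lapply(per_age_sel, `[[`, "candidates"))
      sel <- select_distribution(stats::setNames(
        lapply(rownames(gof$stats), function(f)
          new_gof_result("KS", 0, config$gof_alpha, !(f %in% common))),
        rownames(gof$stats)))
      sel$family
    } else NA_character_

    confirmation <- NULL
    if (is.na(selected)) {
      manifest[["no_adequate_fit"]] <- TRUE
      log_stage(verbose, "no family adequate at every age; skipping model stages")
    } else {
      log_stage(verbose, "selected family: %s", selected)
      stage <- "confirmation"
      confirmation <- withr::with_seed(config$seed + 1L, lapply(
        stats::setNames(as.character(ages), paste0("age_", ages)),
        function(a) {
          x <- trees$dbh_cm[trees$age_years == as.integer(a)]
          f <- gof$fits[[a]][[selected]]
          list(ad = ad_statistic(x, f, B = config$confirm_B),
               cvm = cvm_statistic(x, f, B = config$confirm_B))
        }))
      coeffs <- do.call(rbind, lapply(as.character(ages), function(a) {
        f <- gof$fits[[a]][[selected]]
        data.frame(age_years = as.integer(a), t(f$params), loglik = f$loglik,
                   n = f$n)
      }))
      emit(coeffs, "coefficients_by_age")
    }

    stage <- "shape_stats"
    shp <- shape_table(trees, config$class_width, config$origin)
    emit(shp, "shape_table")

    panel <- correlations <- sw_beta <- sw_gamma <- dummy <- NULL
    rain <- comparison <- scen <- NULL
    if (!is.na(selected) && identical(selected, "weibull2") && !is.null(env)) {
      stage <- "estimator_panel"
      panel <- estimator_panel(trees, env)
      emit(panel, "estimator_panel")

      stage <- "correlations"
      correlations <- correlate_estimators(panel)
      emit(correlations, "correlations")

      stage <- "stepwise"
      covars <- correlations$variable
      sw_beta <- stepwise_select("beta_hat", covars, panel,
                                 config$alpha_enter, config$alpha_stay,
                                 config$report_alpha)
      sw_gamma <- stepwise_select("gamma_hat", covars, panel,
                                  config$alpha_enter, config$alpha_stay,
                                  config$report_alpha)
      emit(stepwise_report(sw_beta, "beta_hat"), "stepwise_beta")
      emit(stepwise_report(sw_gamma, "gamma_hat"), "stepwise_gamma")

      stage <- "dummy_site"
      dummy <- dummy_site_model(panel, "beta_hat", "prec_mm")
      emit(data.frame(response = "beta_hat", covariate = "prec_mm",
                      f_statistic = dummy$f_statistic, p_value = dummy$p_value,
                      site_effect = dummy$site_effect), "dummy_site")

      stage <- "rainfall_model"
      rain <- estimate_rainfall_model(panel)
      emit(data.frame(parameter = c("gamma_intercept", "gamma_slope",
                                    "beta_intercept", "beta_slope"),
                      value = c(rain$model$gamma_intercept, rain$model$gamma_slope,
                                rain$model$beta_intercept, rain$model$beta_slope)),
           "rainfall_model")

      stage <- "predicted_vs_fitted"
      comparison <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
        fitted <- new_fitted_dist("weibull2",
                                  c(shape = panel$gamma_hat[i],
                                    scale = panel$beta_hat[i]), NA_real_, 0L)
        n_eff <- sum(trees$site_id == panel$site_id[i] &
                       trees$age_years == panel$age_years[i])
        r <- compare_predicted_vs_fitted(rain$model, panel$prec_mm[i], fitted,
                                         n_eff, config$curve_alpha)
        data.frame(site_id = panel$site_id[i], age_years = panel$age_years[i],
                   ks2 = r$statistic, p_value = r$p_value,
                   significant = r$significant)
      }))
      emit(comparison, "predicted_vs_fitted")

      stage <- "scenarios"
      scen <- simulate_scenarios(rain$model, config$scenario_levels,
                                 config$scenario_ages, config$class_width,
                                 config$origin)
      emit(scen$summary, "scenario_summary")
      long <- do.call(rbind, lapply(scen$scenarios, function(s) {
        if (!is.null(s$error)) return(NULL)
        cbind(annual_rainfall_mm = s$annual_rainfall_mm,
              age_years = s$age_years, s$classes)
      }))
      emit(long, "scenario_classes")
    }

    stage <- "manifest"
    mf <- data.frame(output = names(manifest),
                     rows = vapply(manifest, function(v)
                       if (isTRUE(v)) NA_integer_ else as.integer(v), integer(1)))
    write_table_csv(mf, file.path(out_dir, "MANIFEST.csv"))

    list(trees = trees, env = env, gof = gof, selection = selected,
         confirmation = confirmation, shape = shp, panel = panel,
         correlations = correlations, stepwise_beta = sw_beta,
         stepwise_gamma = sw_gamma, dummy = dummy, rainfall_model = rain,
         comparison = comparison, scenarios = scen, manifest = manifest,
         out_dir = out_dir)
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    writeLines(c(paste("INCOMPLETE at stage:", stage),
                 conditionMessage(attr(result, "condition"))),
               file.path(out_dir, "MANIFEST.csv"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(attr(result, "condition")))
  }
  invisible(result)
}

stepwise_report <- function(path, response) {
  if (length(path$steps) == 0) {
    return(data.frame(response = response, step = 0L, entered = NA_character_,
                      r_squared = NA_real_, equation = "empty path"))
  }
  do.call(rbind, lapply(seq_along(path$steps), function(i) {
    s <- path$steps[[i]]
    eq <- paste0(response, " = ",
                 paste(sprintf("%+.6g %s", s$coefficients,
                               ifelse(names(s$coefficients) == "(Intercept)", "",
                                      paste0("* ", names(s$coefficients)))),
                       collapse = " "))
    data.frame(response = response, step = i, entered = s$entered,
               r_squared = s$r_squared, equation = eq)
  }))
}
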