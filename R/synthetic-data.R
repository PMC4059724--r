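#' Stand design for the synthetic-study generator
#'
#' Describes one even-aged stand to be simulated: where it is, how old it is,
#' how many trees are measured, the planting spacing, and the mean annual
#' rainfall driving its diameter distribution.
#'
#' @param site_id Character label of the planting site.
#' @param age_years Stand age in whole years, one of 1, 3, 5, 7.
#' @param n_trees Number of trees measured (> 0).
#' @param spacing_m Numeric pair: row and within-row spacing in meters.
#' @param annual_rainfall_mm Mean annual rainfall in mm/yr (> 0).
#' @param seed Integer seed making the stand's draws reproducible.
#' @return An object of class `stand_design`.
#' @examples
#' stand_design("Cristal", 7, 77, c(3, 1.5), 1350, seed = 42)
#' @export
stand_design <- function(site_id, age_years, n_trees, spacing_m = c(3, 1.75),
                         annual_rainfall_mm, seed = 1L) {
  stopifnot(length(site_id) == 1, length(age_years) == 1, length(n_trees) == 1)
  if (!age_years %in% c(1L, 3L, 5L, 7L)) {
    stop("`age_years` must be one of 1, 3, 5, 7")
  }
  if (!is.numeric(n_trees) || n_trees <= 0 || n_trees != round(n_trees)) {
    stop("`n_trees` must be a positive integer")
  }
  if (length(spacing_m) != 2 || any(spacing_m <= 0)) {
    stop("`spacing_m` must be a pair of positive spacings (m)")
  }
  check_positive(annual_rainfall_mm = annual_rainfall_mm)
  structure(list(site_id = as.character(site_id),
                 age_years = as.integer(age_years),
                 n_trees = as.integer(n_trees),
                 spacing_m = as.numeric(spacing_m),
                 annual_rainfall_mm = as.numeric(annual_rainfall_mm),
                 seed = as.integer(seed)),
            class = "stand_design")
}

#' Planting density from spacing
#'
#' Number of planted stems per hectare for a rectangular spacing, e.g.
#' 3 x 1.75 m gives 1904 stems/ha and 3 x 1.5 m gives 2222 stems/ha.
#'
#' @param spacing_m Numeric pair (row, within-row) in meters.
#' @return Integer count of plants per hectare, `floor(10000 / area)`.
#' @examples
#' planting_density(c(3, 1.75))
#' @export
planting_density <- function(spacing_m) {
  if (length(spacing_m) != 2 || !is.numeric(spacing_m) || any(!is.finite(spacing_m)) ||
      any(spacing_m <= 0)) {
    stop("`spacing_m` must be a pair of positive spacings in meters")
  }
  as.integer(floor(10000 / (spacing_m[1] * spacing_m[2])))
}

#' Simulate the tree list of one stand
#'
#' Draws `n_trees` diameters i.i.d. from a two-parameter Weibull. Parameters
#' come either from an explicit (`shape`, `scale`) pair or from a rainfall
#' model (see [rainfall_weibull_model()]), in which case accumulated rainfall
#' is `annual_rainfall_mm * age_years`. Draws are reproducible: the stand's
#' `seed` scopes the RNG locally, leaving the global RNG state untouched.
#'
#' @param design A [stand_design()].
#' @param shape,scale Explicit Weibull parameters (both or neither).
#' @param model A `rainfall_weibull` model used when `shape`/`scale` are
#'   missing; rainfall outside the model's valid range is an error naming
#'   the offending parameter.
#' @param plot_id Plot label attached to every record (the reference design
#'   pools the slope-position plots of a stand, so a single label suffices).
#' @return `data.frame` with columns `site_id`, `plot_id`, `age_years`,
#'   `dbh_cm` and `n_trees` rows.
#' @examples
#' d <- stand_design("Cristal", 1, 112, c(3, 1.75), 1350, seed = 7)
#' trees <- generate_stand(d, shape = 4.115712, scale = 5.606776)
#' @export
generate_stand <- function(design, shape = NULL, scale = NULL, model = NULL,
                           plot_id = "P1") {
  stopifnot(inherits(design, "stand_design"))
  if (is.null(shape) != is.null(scale)) {
    stop("supply both `shape` and `scale`, or neither")
  }
  if (is.null(shape)) {
    if (is.null(model)) stop("supply either explicit (shape, scale) or a rainfall model")
    prec <- design$annual_rainfall_mm * design$age_years
    par <- predict_params(model, prec)
    shape <- par[["shape"]]; scale <- par[["scale"]]
  }
  check_positive(shape = shape, scale = scale)
  dbh <- withr::with_seed(design$seed,
                          stats::rweibull(design$n_trees, shape, scale))
  data.frame(site_id = design$site_id,
             plot_id = plot_id,
             age_years = design$age_years,
             dbh_cm = dbh)
}

#' Default covariate-generation configuration for synthetic studies
#'
#' Ranges and climate normals used by [generate_study()] when emitting the
#' per-stand environmental table. Meteorological accumulations grow with
#' stand age; soil chemistry is drawn once per stand from uniform ranges
#' typical of acid subtropical surface horizons (0-20 cm).
#'
#' @param rg_per_year Mean annual global solar radiation accumulation
#'   (MJ m-2 yr-1).
#' @param t_avg_mean,t_avg_sd Annual mean air temperature normal and
#'   between-stand spread (deg C).
#' @param rh_mean,rh_sd Relative humidity normal and spread (%).
#' @param soil_ranges Named list of `c(lo, hi)` uniform ranges for the 13
#'   surface-soil chemistry variables.
#' @return A list, to pass as `env_config` to [generate_study()].
#' @export
env_config_default <- function(rg_per_year = 5500,
                               t_avg_mean = 18.5, t_avg_sd = 0.6,
                               rh_mean = 80, rh_sd = 3,
                               soil_ranges = NULL) {
  if (is.null(soil_ranges)) {
    soil_ranges <- list(
      pH = c(4.2, 5.5), ISMP = c(5.0, 6.2), clay_pct = c(15, 45),
      om_pct = c(1.5, 4.5), P = c(2, 12), K = c(40, 160),
      Al = c(0.3, 2.5), Ca = c(0.5, 4), Mg = c(0.3, 2),
      H_Al = c(3, 12), CEC_pH7 = c(6, 18),
      base_sat_pct = c(15, 60), al_sat_pct = c(5, 55)
    )
  }
  list(rg_per_year = rg_per_year, t_avg_mean = t_avg_mean, t_avg_sd = t_avg_sd,
       rh_mean = rh_mean, rh_sd = rh_sd, soil_ranges = soil_ranges)
}

#' Generate a complete synthetic study (tree table + environmental table)
#'
#' Simulates every stand of a design list and assembles the per-stand
#' environmental covariate table: accumulated rainfall (mm, planting to
#' measurement), cumulative global solar radiation, air temperatures,
#' relative humidity and the 13 surface-soil chemistry variables.
#'
#' @param designs Non-empty list of [stand_design()]s with unique
#'   site-by-age keys.
#' @param model Optional `rainfall_weibull` model generating diameters from
#'   each stand's accumulated rainfall; the package default when neither
#'   `model` nor `params_by_age` is supplied.
#' @param params_by_age Optional `data.frame` with `age_years`, `shape`,
#'   `scale` giving explicit generating parameters per age (e.g.
#'   [wattle_age_coefficients()]).
#' @param env_config Covariate configuration, see [env_config_default()].
#' @return List with `trees` (one row per tree) and `env` (one row per
#'   stand, class `env_table`).
#' @examples
#' study <- generate_study(wattle_study_design())
#' nrow(study$trees)  # 765
#' @export
generate_study <- function(designs, model = NULL, params_by_age = NULL,
                           env_config = env_config_default()) {
  if (length(designs) == 0) stop("`designs` must be non-empty")
  keys <- vapply(designs, function(d) paste(d$site_id, d$age_years, sep = ":"),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate site:age design keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  if (is.null(model) && is.null(params_by_age)) model <- rainfall_weibull_model()

  trees <- vector("list", length(designs))
  env_rows <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    if (!is.null(params_by_age)) {
      row <- params_by_age[params_by_age$age_years == d$age_years, , drop = FALSE]
      if (nrow(row) != 1) stop("no generating parameters for age ", d$age_years)
      trees[[i]] <- generate_stand(d, shape = row$shape, scale = row$scale)
    } else {
      trees[[i]] <- generate_stand(d, model = model)
    }
    env_rows[[i]] <- withr::with_seed(d$seed + 100000L,
                                      generate_env_row(d, env_config))
  }
  env <- do.call(rbind, env_rows)
  class(env) <- c("env_table", "data.frame")
  list(trees = do.call(rbind, trees), env = env)
}

generate_env_row <- function(d, cfg) {
  age <- d$age_years
  soil <- vapply(cfg$soil_ranges, function(r) stats::runif(1, r[1], r[2]),
                 numeric(1))
  t_avg <- stats::rnorm(1, cfg$t_avg_mean, cfg$t_avg_sd)
  row <- data.frame(
    site_id = d$site_id,
    age_years = age,
    prec_mm = d$annual_rainfall_mm * age,
    rg = cfg$rg_per_year * age * stats::runif(1, 0.95, 1.05),
    t_max = t_avg + stats::runif(1, 5.5, 7),
    t_min = t_avg - stats::runif(1, 5.5, 7),
    t_avg = t_avg,
    rh_pct = min(100, max(0, stats::rnorm(1, cfg$rh_mean, cfg$rh_sd)))
  )
  cbind(row, as.data.frame(as.list(soil)))
}

#' Angstrom-Prescott estimate of global solar radiation
#'
#' Global incident radiation from extraterrestrial radiation and relative
#' sunshine duration: `Rg = Ra * (a + b * n/N)`. The calibration
#' coefficients `a` and `b` are site-specific configuration; no universal
#' default is assumed.
#'
#' @param extraterrestrial Extraterrestrial radiation `Ra` (same energy
#'   units as the result), non-negative.
#' @param sunshine_fraction Relative sunshine duration `n/N` in `[0, 1]`.
#' @param a,b Angstrom-Prescott coefficients.
#' @return Estimated global radiation, `Ra * (a + b * n/N)`.
#' @examples
#' angstrom_radiation(30, 1, a = 0.25, b = 0.50)  # full-sun bound: 22.5
#' @export
angstrom_radiation <- function(extraterrestrial, sunshine_fraction, a, b) {
  if (any(extraterrestrial < 0)) stop("`extraterrestrial` must be non-negative")
  if (any(sunshine_fraction < 0 | sunshine_fraction > 1)) {
    stop("`sunshine_fraction` must lie in [0, 1]")
  }
  extraterrestrial * (a + b * sunshine_fraction)
}
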