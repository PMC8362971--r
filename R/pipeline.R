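# Pipeline orchestration: fit every trait model from an observation set,
# simulate growth parameters over temperatures, and map establishment /
# generation indices — each step reproducible from one seed, with output
# sidecars recording the settings used.  These functions are the
# package's command surface; each is a thin wrapper over the module
# functions and can be scripted directly.

#' Fit all trait models from life-history observations
#'
#' Runs the full model-building workflow: mean development rates per
#' temperature feed the linear degree-day and Logan fits; individual
#' development times and adult death days feed the shared-slope
#' distributions; per-temperature mortality proportions, mean lifetime
#' fecundities and senescence rates feed the nonlinear curve fits; and
#' pooled normalised cumulative oviposition feeds the age-schedule fit.
#' Traits whose observations are missing are skipped with a warning,
#' yielding a partial archive that [run_simulate()] refuses.
#'
#' @param obs a [life_history()] object or path to an observations CSV.
#' @param archive_path optional path: write the fitted models as a JSON
#'   archive.
#' @param links named list of links for the distribution fits (defaults:
#'   dev_time `"logit"`, male_longevity `"cloglog"`, female_longevity
#'   `"logit"`).
#' @param n_starts multi-start count for the nonlinear fits (default 32).
#' @param seed seed for the start grids (default 1).
#' @param mortality_augmentation optional data frame (`x`, `y`) of
#'   pseudo-observations added to the mortality fit (off by default; the
#'   y-values must be supplied by the user).
#' @param max_longevity cap (days) on expected adult longevity used when
#'   normalising female ages for the oviposition fit (default 25).
#' @param linear_max_temp upper temperature bound (degrees C) for the
#'   linear degree-day fit, which is only valid on the middle, linear
#'   portion of the rate-temperature curve (default 30).
#' @return a list with `models` (a [thermal_model_set()], or a partial
#'   named list if traits were missing), `report` (one row per fitted
#'   trait: family, R2, AIC, convergence) and `complete` (logical).
#' @export
run_fit <- function(obs, archive_path = NULL,
                    links = list(dev_time = "logit",
                                 male_longevity = "cloglog",
                                 female_longevity = "logit"),
                    n_starts = 32, seed = 1,
                    mortality_augmentation = NULL, max_longevity = 25,
                    linear_max_temp = 30) {
  if (is.character(obs)) obs <- read_life_history(obs)
  stopifnot(inherits(obs, "life_history"))
  models <- list()
  report <- list()
  note <- function(trait, fit) {
    report[[length(report) + 1]] <<- data.frame(
      trait = trait, family = fit$family, r_squared = fit$r_squared,
      aic = fit$aic, converged = fit$converged)
  }

  im <- obs$immatures
  surv <- im[im$survived %in% TRUE & is.finite(im$dev_days), ]
  if (nrow(surv)) {
    agg <- stats::aggregate(dev_days ~ temperature, data = surv, FUN = mean)
    rates <- 1 / agg$dev_days
    lin_keep <- agg$temperature <= linear_max_temp
    lin <- fit_linear_thresholds(agg$temperature[lin_keep], rates[lin_keep])
    models$dev_rate_linear <- lin$model
    note("dev_rate_linear", lin$fit)
    logan <- fit_nonlinear("logan1", agg$temperature, rates,
                           n_starts = n_starts, seed = derive_seed(seed, 1))
    models$dev_rate <- logan$model
    note("dev_rate", logan$fit)
    dd <- fit_shared_slope_distribution(obs, "dev_time",
                                        links$dev_time %||% "logit")
    models$dev_time_dist <- dd$model
    note("dev_time_dist", dd$fit)
  } else {
    warning("no immature development observations; development models not fitted")
  }

  if (nrow(im)) {
    agg <- stats::aggregate(survived ~ temperature, data = im,
                            FUN = function(z) mean(!z))
    counts <- stats::aggregate(survived ~ temperature, data = im,
                               FUN = length)$survived
    # inverse binomial variance weights, clipped away from the 0/1 edges
    p_clip <- pmin(pmax(agg$survived, 1 / (2 * counts)),
                   1 - 1 / (2 * counts))
    mort <- fit_nonlinear("mortality_curve", agg$temperature, agg$survived,
                          n_starts = n_starts, seed = derive_seed(seed, 2),
                          augmentation = mortality_augmentation,
                          weights = counts / (p_clip * (1 - p_clip)))
    models$immature_mortality <- mort$model
    note("immature_mortality", mort$fit)
  }

  ad <- obs$adults
  for (sex in c("F", "M")) {
    sub <- ad[ad$sex == sex, ]
    trait <- if (sex == "F") "female" else "male"
    if (nrow(sub) == 0) {
      warning("no ", trait, " adult observations; senescence not fitted")
      next
    }
    agg <- stats::aggregate(death_day ~ temperature, data = sub, FUN = mean)
    sen <- fit_nonlinear("ratkowsky", agg$temperature, 1 / agg$death_day,
                         n_starts = n_starts,
                         seed = derive_seed(seed, 3, as.integer(sex == "M")))
    models[[paste0(trait, "_senescence")]] <- sen$model
    note(paste0(trait, "_senescence"), sen$fit)
    dist_trait <- paste0(trait, "_longevity")
    ld <- fit_shared_slope_distribution(obs, dist_trait,
                                        links[[dist_trait]] %||% "logit")
    models[[paste0(trait, "_longevity_dist")]] <- ld$model
    note(paste0(trait, "_longevity_dist"), ld$fit)
  }

  fem <- ad[ad$sex == "F", ]
  if (nrow(obs$eggs) == 0 || nrow(fem) == 0) {
    warning("no fecundity observations; fecundity and oviposition-age ",
            "models not fitted, simulation will be blocked")
  } else {
    totals <- stats::aggregate(eggs ~ temperature + id, data = obs$eggs,
                               FUN = sum)
    per_fem <- merge(fem[, c("temperature", "id")], totals,
                     by = c("temperature", "id"), all.x = TRUE)
    per_fem$eggs[is.na(per_fem$eggs)] <- 0
    agg <- stats::aggregate(eggs ~ temperature, data = per_fem, FUN = mean)
    fc <- fit_nonlinear("fecundity_curve", agg$temperature, agg$eggs,
                        n_starts = n_starts, seed = derive_seed(seed, 4))
    models$fecundity <- fc$model
    note("fecundity", fc$fit)

    if (!is.null(models$female_senescence)) {
      pooled <- oviposition_curve_data(obs, models$female_senescence,
                                       max_longevity)
      ov <- fit_nonlinear("oviposition_age", pooled$x, pooled$y,
                          n_starts = n_starts, seed = derive_seed(seed, 5))
      models$oviposition_age <- ov$model
      note("oviposition_age", ov$fit)
    }
  }

  required <- c("dev_rate", "dev_rate_linear", "dev_time_dist",
                "immature_mortality", "fecundity", "oviposition_age",
                "female_senescence", "male_senescence")
  complete <- all(required %in% names(models))
  out_models <- if (complete) {
    set <- thermal_model_set(
      models$dev_rate, models$dev_rate_linear, models$dev_time_dist,
      models$immature_mortality, models$fecundity, models$oviposition_age,
      models$female_senescence, models$male_senescence,
      models$female_longevity_dist, models$male_longevity_dist)
    for (s in names(models)) attr(set[[s]], "fit") <- attr(models[[s]], "fit")
    set
  } else {
    models
  }
  if (!is.null(archive_path)) write_model_archive(out_models, archive_path)
  list(models = out_models, report = do.call(rbind, report),
       complete = complete)
}

# Pooled (normalised age, cumulative proportion) points for the
# oviposition-age fit: per female, cumulative eggs over her own total,
# against age normalised by the fitted expected longevity at her
# temperature.
oviposition_curve_data <- function(obs, female_senescence, max_longevity) {
  eggs <- obs$eggs[order(obs$eggs$id, obs$eggs$adult_age), ]
  out_x <- numeric(0)
  out_y <- numeric(0)
  for (id in unique(eggs$id)) {
    sub <- eggs[eggs$id == id, ]
    total <- sum(sub$eggs)
    if (total <= 0) next
    lf <- expected_longevity(female_senescence, sub$temperature[1],
                             max_longevity)
    if (!is.finite(lf) || lf <= 0) next
    out_x <- c(out_x, sub$adult_age / lf)
    out_y <- c(out_y, cumsum(sub$eggs) / total)
  }
  data.frame(x = out_x, y = out_y)
}

#' Simulate growth parameters from a fitted model archive
#'
#' @param models a [thermal_model_set()], or a path to a JSON model
#'   archive; a partial archive raises a dependency error naming the
#'   missing models.
#' @param temperatures temperatures (degrees C) to simulate (default
#'   15 to 30 by 3).
#' @param config a [cohort_config()] template (temperature overridden per
#'   run).
#' @param csv_path optional path for the per-temperature summary CSV; a
#'   JSON sidecar (`<csv_path>.json`) records the seed and settings.
#' @param method `"lotka"` (default) or `"approximation"`.
#' @return the [growth_params_over_temperature()] result; with a single
#'   replicate the SE columns are dropped.
#' @export
run_simulate <- function(models, temperatures = seq(15, 30, by = 3),
                         config = cohort_config(temperatures[1]),
                         csv_path = NULL, method = "lotka") {
  if (is.character(models)) models <- read_model_archive(models)
  if (!inherits(models, "thermal_model_set")) {
    required <- c("dev_rate", "dev_rate_linear", "dev_time_dist",
                  "immature_mortality", "fecundity", "oviposition_age",
                  "female_senescence", "male_senescence")
    missing <- setdiff(required, names(models))
    stop_invalid("incomplete model archive; missing: ",
                 paste(missing, collapse = ", "))
  }
  res <- growth_params_over_temperature(models, temperatures, config,
                                        method = method)
  if (config$replicates == 1) {
    res$summary <- res$summary[, !grepl("_se$", names(res$summary))]
  }
  if (!is.null(csv_path)) {
    utils::write.csv(res$summary, csv_path, row.names = FALSE)
    utils::write.csv(res$replicates,
                     sub("\\.csv$", "_replicates.csv", csv_path),
                     row.names = FALSE)
    sidecar <- list(seed = config$seed, n_eggs = config$n_eggs,
                    replicates = config$replicates,
                    sex_ratio = config$sex_ratio,
                    max_longevity = config$max_longevity,
                    temperatures = temperatures, method = method)
    jsonlite::write_json(sidecar, paste0(csv_path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Map establishment and generation indices from a climate stack
#'
#' Produces the four raster products: EI, GI, the EI suitability
#' classification and (when a future climate is given) the EI change
#' grid, writing them as ESRI ASCII grids with a JSON sidecar of settings.
#'
#' @param models a [thermal_model_set()] or archive path.
#' @param climate a [climate_grid()] or a directory readable by
#'   [read_climate_grid()].
#' @param out_dir optional output directory for the rasters and sidecar.
#' @param future_climate optional second climate (grid or directory) for
#'   the change product.
#' @param breaks a [suitability_breaks()] (default the strict preset).
#' @param lethal_threshold mortality level treated as total (default
#'   0.99).
#' @param tc_step lattice resolution (degrees C) for the generation-time
#'   interpolation (default 1).
#' @param config a [cohort_config()] template for the Tc lattice.
#' @return a list with `ei`, `gi`, `classification` and (if a future
#'   climate was given) `change`.
#' @export
run_map <- function(models, climate, out_dir = NULL, future_climate = NULL,
                    breaks = suitability_breaks(), lethal_threshold = 0.99,
                    tc_step = 1, config = cohort_config(20, replicates = 1)) {
  if (is.character(models)) models <- read_model_archive(models)
  stopifnot(inherits(models, "thermal_model_set"))
  if (is.character(climate)) climate <- read_climate_grid(climate)
  if (is.character(future_climate)) {
    future_climate <- read_climate_grid(future_climate)
  }
  tc_fun <- make_tc_function(models, step = tc_step, config = config)
  ei <- ei_map(climate, models$immature_mortality, lethal_threshold)
  gi <- gi_map(climate, tc_fun)
  cls <- classify_suitability(ei, breaks)
  out <- list(ei = ei, gi = gi, classification = cls)
  if (!is.null(future_climate)) {
    ei_future <- ei_map(future_climate, models$immature_mortality,
                        lethal_threshold)
    out$change <- index_difference(ei_future, ei)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_index_grid(ei, file.path(out_dir, "ei.asc"))
    write_index_grid(gi, file.path(out_dir, "gi.asc"))
    cls_codes <- matrix(match(cls, breaks$labels), nrow(cls), ncol(cls))
    write_ascii_grid(cls_codes, file.path(out_dir, "classification.asc"),
                     ei$xll, ei$yll, ei$cellsize)
    if (!is.null(out$change)) {
      write_index_grid(out$change, file.path(out_dir, "ei_change.asc"))
    }
    sidecar <- list(lethal_threshold = lethal_threshold,
                    breaks = breaks$thresholds,
                    class_labels = breaks$labels,
                    tc_step = tc_step, seed = config$seed,
                    n_eggs = config$n_eggs,
                    classification_codes = seq_along(breaks$labels))
    jsonlite::write_json(sidecar, file.path(out_dir, "map_settings.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
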