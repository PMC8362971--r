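# JSON model archive: one document holding every fitted model with its
# function name, parameter values and (when available) fit statistics.
# Field names are fixed; round-tripping a thermal_model_set through the
# archive is lossless at full double precision.

model_to_record <- function(model) {
  fit <- attr(model, "fit")
  rec <- switch(class(model)[1],
    linear_rate_model = list(
      `function` = "linear",
      parameters = list(a = model$a, b = model$b),
      derived = list(t_min = model$t_min, k = model$k)),
    logan_rate_model = list(
      `function` = "logan1",
      parameters = list(gamma = model$gamma, rho = model$rho,
                        t_max = model$t_max, v = model$v)),
    mortality_curve = list(
      `function` = "mortality_curve",
      parameters = list(t_opt = model$t_opt, b_low = model$b_low,
                        b_high = model$b_high, h = model$h,
                        lethal_level = model$lethal_level),
      derived = list(t_lethal_low = model$t_lethal_low,
                     t_lethal_high = model$t_lethal_high)),
    fecundity_curve = list(
      `function` = "fecundity_curve",
      parameters = list(t_op = model$t_op, b1 = model$b1,
                        b_high = model$b_high, h = model$h)),
    oviposition_age_model = list(
      `function` = "oviposition_age",
      parameters = list(a = model$a, b = model$b)),
    senescence_model = list(
      `function` = "ratkowsky",
      parameters = list(b = model$b, t_b = model$t_b)),
    devtime_distribution = list(
      `function` = "shared_slope",
      link = model$link,
      parameters = list(slope_b = model$slope_b,
                        intercepts = as.list(model$intercepts))),
    stop_invalid("cannot archive object of class ", class(model)[1]))
  if (!is.null(fit)) {
    rec$fit <- list(r_squared = fit$r_squared, aic = fit$aic,
                    residual_df = fit$residual_df,
                    converged = fit$converged,
                    n_starts_used = fit$n_starts_used %||% NA,
                    augmented = isTRUE(fit$augmented))
  }
  rec
}

record_to_model <- function(rec) {
  p <- rec$parameters
  model <- switch(rec$`function`,
    linear = linear_rate_model(p$a, p$b),
    logan1 = logan_rate_model(p$gamma, p$rho, p$t_max, p$v),
    mortality_curve = mortality_curve(p$t_opt, p$b_low, p$b_high, p$h,
                                      p$lethal_level %||% 0.999),
    fecundity_curve = fecundity_curve(p$t_op, p$b1, p$b_high, p$h),
    oviposition_age = oviposition_age_model(p$a, p$b),
    ratkowsky = senescence_model(p$b, p$t_b),
    shared_slope = devtime_distribution(rec$link, p$slope_b,
                                        unlist(p$intercepts) %||% numeric()),
    stop_invalid("unknown model function '", rec$`function`, "' in archive"))
  if (!is.null(rec$fit)) attr(model, "fit") <- rec$fit
  model
}

archive_slots <- c("dev_rate", "dev_rate_linear", "dev_time_dist",
                   "immature_mortality", "fecundity", "oviposition_age",
                   "female_senescence", "male_senescence",
                   "female_longevity_dist", "male_longevity_dist")

#' Write a model set to a JSON archive
#'
#' @param models a [thermal_model_set()], or a plain named list holding a
#'   subset of its slots (a partial archive from an incomplete fit).
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_model_archive <- function(models, path) {
  slots <- archive_slots[archive_slots %in% names(models)]
  recs <- list()
  for (s in slots) {
    if (!is.null(models[[s]])) recs[[s]] <- model_to_record(models[[s]])
  }
  doc <- list(format = "phenotherm-model-archive", version = 1L,
              models = recs)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a model set from a JSON archive
#'
#' @param path archive file written by [write_model_archive()].
#' @return a [thermal_model_set()] if all required slots are present,
#'   otherwise a plain named list of the models found (a partial archive).
#' @export
read_model_archive <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "phenotherm-model-archive")) {
    stop_invalid("not a phenotherm model archive: ", path)
  }
  models <- lapply(doc$models, record_to_model)
  required <- c("dev_rate", "dev_rate_linear", "dev_time_dist",
                "immature_mortality", "fecundity", "oviposition_age",
                "female_senescence", "male_senescence")
  if (all(required %in% names(models))) {
    set <- thermal_model_set(
      dev_rate = models$dev_rate,
      dev_rate_linear = models$dev_rate_linear,
      dev_time_dist = models$dev_time_dist,
      immature_mortality = models$immature_mortality,
      fecundity = models$fecundity,
      oviposition_age = models$oviposition_age,
      female_senescence = models$female_senescence,
      male_senescence = models$male_senescence,
      female_longevity_dist = models$female_longevity_dist,
      male_longevity_dist = models$male_longevity_dist)
    for (s in names(models)) attr(set[[s]], "fit") <- attr(models[[s]], "fit")
    return(set)
  }
  models
}
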