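# Synthetic-data generation: individual-level life-history observations
# drawn from a known ("truth") thermal model set, and synthetic monthly
# climate grids, so that fitting, simulation and mapping are all testable
# end to end without external downloads.

#' Reference thermal model set for *Diachasmimorpha longicaudata*
#'
#' A complete compiled model set emulating the thermal biology of the
#' braconid parasitoid *D. longicaudata* reared on *Bactrocera dorsalis*:
#' egg-to-adult development between roughly 10 and 33.7 degrees C
#' (thermal constant ~333 degree-days), total immature mortality near 10
#' and 34 degrees C with a survival optimum at 28 degrees C, lifetime
#' fecundity peaking around 220 eggs per female near 28 degrees C (about
#' 177 at 25 and a handful at 35), and adult senescence parabolas with
#' vertices near 21 degrees C.  Used as the default ground truth of the
#' synthetic-data generator and as a ready-made example model set.
#'
#' @return a [thermal_model_set()].
#' @export
longicaudata_models <- function() {
  dev_linear <- linear_rate_model(a = -0.02911507, b = 0.003005752)
  dev_logan <- logan_rate_model(gamma = 0.0869340, rho = 0.1966278,
                                t_max = 33.6927, v = 5.072962)
  dev_dist <- devtime_distribution(
    "logit", slope_b = 15.56,
    intercepts = c(`15` = -65.67, `20` = -53.71, `25` = -45.90,
                   `30` = -43.63))
  mort <- mortality_curve(t_opt = 28, b_low = 4.5, b_high = 0.6, h = 0.87)
  fec <- fecundity_curve(t_op = 28, b1 = 3.8, b_high = 1.2, h = 220)
  ovi <- oviposition_age_model(a = 0.73, b = 1.35)
  sen_f <- senescence_model(b = 0.0031, t_b = 21.12)
  sen_m <- senescence_model(b = 0.0022, t_b = 20.61)
  long_f <- devtime_distribution("logit", slope_b = 2.41)
  long_m <- devtime_distribution("cloglog", slope_b = 1.49)
  thermal_model_set(dev_rate = dev_logan, dev_rate_linear = dev_linear,
                    dev_time_dist = dev_dist, immature_mortality = mort,
                    fecundity = fec, oviposition_age = ovi,
                    female_senescence = sen_f, male_senescence = sen_m,
                    female_longevity_dist = long_f,
                    male_longevity_dist = long_m)
}

#' Ground-truth configuration for the life-history generator
#'
#' @param models the truth [thermal_model_set()] (default
#'   [longicaudata_models()]).
#' @param n_immature individuals exposed as eggs per temperature
#'   (default 150).
#' @param n_adults adults of each sex followed per temperature
#'   (default 50).
#' @param immature_temps temperatures of the immature-development
#'   experiment (default 15, 20, 25, 30, 35).
#' @param adult_temps temperatures of the adult longevity/oviposition
#'   experiment (default 15, 20, 25, 30, 32.5, 35; adults are introduced
#'   freshly emerged, so these extend beyond the immatures' viable range).
#' @param dispersion negative-binomial size for lifetime egg totals
#'   (`Inf` = Poisson, the default).
#' @param max_longevity cap (days) on expected adult longevity from the
#'   senescence parabola (default 25).
#' @param daily_cap optional cap on eggs recorded per female-day
#'   (emulating a limited daily host supply); `NULL` disables it.
#' @param seed generator seed.
#' @return an object of class `generator_truth`.
#' @export
generator_truth <- function(models = longicaudata_models(),
                            n_immature = 150, n_adults = 50,
                            immature_temps = c(15, 20, 25, 30, 35),
                            adult_temps = c(15, 20, 25, 30, 32.5, 35),
                            dispersion = Inf, max_longevity = 25,
                            daily_cap = NULL, seed = 1) {
  stopifnot(inherits(models, "thermal_model_set"),
            n_immature >= 1, n_adults >= 1)
  structure(list(models = models, n_immature = as.integer(n_immature),
                 n_adults = as.integer(n_adults),
                 immature_temps = immature_temps,
                 adult_temps = adult_temps, dispersion = dispersion,
                 max_longevity = max_longevity, daily_cap = daily_cap,
                 seed = as.integer(seed)),
            class = "generator_truth")
}

#' Generate individual-level life-history observations from a truth model
#'
#' Emulates the constant-temperature experimental design: per immature
#' temperature, eggs survive with probability `1 - m(T)` and survivors'
#' development times are drawn from the truth distribution around the
#' Logan-model median (at a temperature where the development rate is
#' zero no individual emerges); per adult temperature, freshly emerged
#' males and females die at ages drawn from the longevity distributions
#' and females lay lifetime egg totals spread over their lived days by
#' the oviposition-age schedule.
#'
#' @param truth a [generator_truth()].
#' @param seed optional seed overriding the truth's.
#' @return a [life_history()] object.
#' @export
generate_life_history <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "generator_truth"))
  mods <- truth$models
  with_local_seed(seed %||% truth$seed, {
    next_id <- 0
    im_list <- list()
    for (tt in truth$immature_temps) {
      n <- truth$n_immature
      m <- mortality(mods$immature_mortality, tt)
      r <- rate_logan(mods$dev_rate, tt)
      survived <- if (r > 0) stats::runif(n) >= m else rep(FALSE, n)
      dev <- rep(NA_real_, n)
      if (any(survived)) {
        dev[survived] <- ceiling(
          sample_dev_time(mods$dev_time_dist, 1 / r, sum(survived)))
      }
      im_list[[length(im_list) + 1]] <- data.frame(
        temperature = tt, id = next_id + seq_len(n),
        survived = survived, dev_days = dev)
      next_id <- next_id + n
    }

    ad_list <- list()
    egg_list <- list()
    for (tt in truth$adult_temps) {
      lf <- expected_longevity(mods$female_senescence, tt,
                               truth$max_longevity)
      lm_ <- expected_longevity(mods$male_senescence, tt,
                                truth$max_longevity)
      n <- truth$n_adults
      draw <- function(dist, med) {
        if (!is.finite(med) || med <= 0) return(rep(1, n))
        if (is.null(dist)) rep(med, n) else sample_dev_time(dist, med, n)
      }
      death_f <- pmax(1, ceiling(draw(mods$female_longevity_dist, lf)))
      death_m <- pmax(1, ceiling(draw(mods$male_longevity_dist, lm_)))
      ids_f <- next_id + seq_len(n); next_id <- next_id + n
      ids_m <- next_id + seq_len(n); next_id <- next_id + n
      ad_list[[length(ad_list) + 1]] <- data.frame(
        temperature = tt, id = c(ids_f, ids_m),
        sex = rep(c("F", "M"), each = n),
        death_day = c(death_f, death_m))

      mu <- fecundity(mods$fecundity, tt)
      totals <- draw_egg_totals(n, mu, truth$dispersion)
      alloc <- allocate_eggs(totals, death_f, mods$oviposition_age, lf, 1)
      if (nrow(alloc)) {
        if (!is.null(truth$daily_cap)) {
          alloc$eggs <- pmin(alloc$eggs, truth$daily_cap)
        }
        egg_list[[length(egg_list) + 1]] <- data.frame(
          temperature = tt, id = ids_f[alloc$idx],
          adult_age = alloc$adult_age, eggs = alloc$eggs)
      }
    }
    life_history(immatures = do.call(rbind, im_list),
                 adults = do.call(rbind, ad_list),
                 eggs = if (length(egg_list)) do.call(rbind, egg_list))
  })
}

#' Generate a synthetic monthly climate grid
#'
#' Three spatial/seasonal patterns: `"constant"` (every cell and month
#' identical), `"latitudinal-gradient"` (mean temperature varying
#' linearly from the first to the last row, seasonally flat) and
#' `"seasonal-sinusoid"` (a sinusoidal annual cycle around a mean, same
#' in every cell).  A fixed diurnal range separates tmin from tmax.
#'
#' @param pattern one of `"constant"`, `"latitudinal-gradient"`,
#'   `"seasonal-sinusoid"`.
#' @param nrow,ncol grid shape (each >= 1).
#' @param tmean annual mean temperature (degrees C); for the gradient
#'   pattern a length-2 vector giving the means of the first and last row.
#' @param diurnal_range fixed tmax - tmin (degrees C, >= 0, default 5).
#' @param amplitude seasonal half-amplitude (degrees C, default 0; only
#'   used by `"seasonal-sinusoid"`).
#' @param peak_month month (1-12) at which the sinusoid peaks (default 1).
#' @param xll,yll,cellsize,crs georeferencing passed to [climate_grid()].
#' @return a [climate_grid()] with the generating parameters attached as
#'   attribute `"pattern"`.
#' @export
generate_climate_grid <- function(pattern = c("constant",
                                              "latitudinal-gradient",
                                              "seasonal-sinusoid"),
                                  nrow = 10, ncol = 10, tmean = 20,
                                  diurnal_range = 5, amplitude = 0,
                                  peak_month = 1, xll = 0, yll = 0,
                                  cellsize = 1, crs = "unspecified") {
  pattern <- match.arg(pattern)
  if (nrow < 1 || ncol < 1) stop_invalid("grid shape must be >= 1 x 1")
  if (diurnal_range < 0) {
    stop_invalid("diurnal_range must be >= 0 (tmin <= tmax)")
  }
  row_mean <- switch(pattern,
    constant = rep(tmean[1], nrow),
    `latitudinal-gradient` = {
      if (length(tmean) != 2) {
        stop_invalid("gradient pattern needs tmean = c(first_row, last_row)")
      }
      seq(tmean[1], tmean[2], length.out = nrow)
    },
    `seasonal-sinusoid` = rep(tmean[1], nrow))
  month_anom <- if (pattern == "seasonal-sinusoid") {
    amplitude * cos(2 * pi * ((1:12) - peak_month) / 12)
  } else {
    rep(0, 12)
  }
  tmin <- array(NA_real_, c(nrow, ncol, 12))
  tmax <- array(NA_real_, c(nrow, ncol, 12))
  for (m in 1:12) {
    mean_m <- matrix(rep(row_mean + month_anom[m], ncol), nrow, ncol)
    tmin[, , m] <- mean_m - diurnal_range / 2
    tmax[, , m] <- mean_m + diurnal_range / 2
  }
  g <- climate_grid(tmin, tmax, xll = xll, yll = yll, cellsize = cellsize,
                    crs = crs)
  attr(g, "pattern") <- list(pattern = pattern, tmean = tmean,
                             diurnal_range = diurnal_range,
                             amplitude = amplitude, peak_month = peak_month)
  g
}
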