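# Establishment and generation indices from monthly climate grids.
#
# The establishment index (EI) of a location is one minus the fraction of
# the 365-day year on which immature survival is predicted to be
# (effectively) zero; the generation index (GI) is the mean over Julian
# days of 365 / Tc(T_day), the expected number of generations per year.
# Monthly layers are turned into daily series by periodic cosine
# interpolation anchored at mid-month.

month_lengths <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
month_midpoints <- cumsum(month_lengths) - month_lengths / 2

# For each of the 365 Julian days: the bracketing months (m1 before, m2
# after the day's centre) and the cosine blending weight of m2.
daily_month_weights <- function() {
  t <- seq_len(365) - 0.5
  mids <- month_midpoints
  m1 <- findInterval(t, mids)              # 0 before mid-January
  m2 <- m1 + 1
  wrap_lo <- m1 == 0
  wrap_hi <- m2 == 13
  m1[wrap_lo] <- 12
  m2[wrap_hi] <- 1
  lo <- mids[m1] - ifelse(wrap_lo, 365, 0)
  hi <- mids[ifelse(wrap_hi, 1, m2)] + ifelse(wrap_hi, 365, 0)
  frac <- (t - lo) / (hi - lo)
  data.frame(day = seq_len(365), m1 = m1, m2 = m2,
             w = (1 - cos(pi * frac)) / 2)
}

#' Monthly climate grid
#'
#' Twelve monthly-mean daily-minimum and twelve daily-maximum temperature
#' layers sharing one georeferencing (lower-left corner + square cell
#' size).  Cells that are `NA` in any layer are treated as nodata.
#'
#' @param tmin,tmax numeric arrays of dimension `nrow x ncol x 12`
#'   (degrees C); row 1 is the northernmost row.
#' @param xll,yll coordinates of the lower-left corner (default 0).
#' @param cellsize cell size (default 1).
#' @param crs free-text coordinate reference description (default
#'   `"unspecified"`).
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(tmin, tmax, xll = 0, yll = 0, cellsize = 1,
                         crs = "unspecified") {
  if (length(dim(tmin)) != 3 || dim(tmin)[3] != 12) {
    stop_invalid("tmin must be an nrow x ncol x 12 array")
  }
  if (!identical(dim(tmin), dim(tmax))) {
    stop_invalid("tmin and tmax stacks must share their shape")
  }
  bad <- which(tmin > tmax)
  if (length(bad)) {
    stop_invalid("tmin exceeds tmax in ", length(bad), " cell-months")
  }
  mask <- apply(is.na(tmin) | is.na(tmax), c(1, 2), any)
  structure(list(tmin = tmin, tmax = tmax, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs, nodata_mask = mask),
            class = "climate_grid")
}

#' Daily temperature series for one grid cell
#'
#' Periodic cosine interpolation of the monthly layers, anchored at
#' mid-month (so a day at a month's midpoint takes exactly that month's
#' value); the daily mean is `(min + max)/2`.
#'
#' @param grid a [climate_grid()].
#' @param row,col cell indices.
#' @return a data frame with columns `day` (1..365), `tmin`, `tmax` and
#'   `tmean`; all-`NA` values for a nodata cell.
#' @export
interpolate_daily <- function(grid, row, col) {
  stopifnot(inherits(grid, "climate_grid"))
  w <- daily_month_weights()
  if (grid$nodata_mask[row, col]) {
    return(data.frame(day = w$day, tmin = NA_real_, tmax = NA_real_,
                      tmean = NA_real_))
  }
  mn <- grid$tmin[row, col, ]
  mx <- grid$tmax[row, col, ]
  tmin_d <- (1 - w$w) * mn[w$m1] + w$w * mn[w$m2]
  tmax_d <- (1 - w$w) * mx[w$m1] + w$w * mx[w$m2]
  data.frame(day = w$day, tmin = tmin_d, tmax = tmax_d,
             tmean = (tmin_d + tmax_d) / 2)
}

#' Establishment index of a daily temperature series
#'
#' A day is lethal when the mortality curve evaluated at its mean
#' temperature reaches `lethal_threshold`; with `mode = "extremes"` a day
#' is also lethal when either daily extreme reaches it.  EI = 1 minus the
#' fraction of lethal days.
#'
#' @param series a data frame from [interpolate_daily()] (columns `tmean`
#'   and, for the extremes mode, `tmin`/`tmax`), or a numeric vector of
#'   daily mean temperatures.
#' @param mortality_model a [mortality_curve()].
#' @param lethal_threshold mortality proportion treated as total
#'   (default 0.99).
#' @param mode `"mean"` (default) or `"extremes"`.
#' @return EI in `[0, 1]`, or `NA` for a nodata series.
#' @export
establishment_index <- function(series, mortality_model,
                                lethal_threshold = 0.99,
                                mode = c("mean", "extremes")) {
  mode <- match.arg(mode)
  if (is.data.frame(series)) {
    tmean <- series$tmean
    tlo <- series$tmin
    thi <- series$tmax
  } else {
    tmean <- series
    tlo <- thi <- NULL
  }
  if (all(is.na(tmean))) return(NA_real_)
  lethal <- mortality(mortality_model, tmean) >= lethal_threshold
  if (mode == "extremes" && !is.null(tlo)) {
    lethal <- lethal |
      mortality(mortality_model, tlo) >= lethal_threshold |
      mortality(mortality_model, thi) >= lethal_threshold
  }
  1 - sum(lethal) / length(tmean)
}

#' Generation index of a daily temperature series
#'
#' The mean over Julian days of `365 / Tc(T_day)`; days where the
#' generation time is undefined (outside the viable range) contribute zero
#' generations.
#'
#' @param series daily mean temperatures (numeric vector or a data frame
#'   with a `tmean` column).
#' @param tc_function a function mapping temperature (degrees C) to mean
#'   generation time in days (`NA` or non-positive outside the viable
#'   range), e.g. from [make_tc_function()].
#' @return GI, in generations per year (`NA` for a nodata series).
#' @export
generation_index <- function(series, tc_function) {
  tmean <- if (is.data.frame(series)) series$tmean else series
  if (all(is.na(tmean))) return(NA_real_)
  tc <- tc_function(tmean)
  g <- ifelse(is.finite(tc) & tc > 0, 365 / tc, 0)
  mean(g)
}

#' Interpolated generation-time function from simulated cohorts
#'
#' Simulates growth parameters on a regular temperature lattice and
#' linearly interpolates the mean generation time; outside the lattice's
#' viable range (no reproduction) the returned function gives `NA`, which
#' [generation_index()] counts as zero generations.
#'
#' @param models a [thermal_model_set()].
#' @param range temperature range (degrees C) of the lattice
#'   (default `c(10, 36)`).
#' @param step lattice resolution in degrees C (default 1).
#' @param config a [cohort_config()] template for the lattice simulations.
#' @return a vectorised function temperature -> Tc (days).
#' @export
make_tc_function <- function(models, range = c(10, 36), step = 1,
                             config = cohort_config(range[1],
                                                    replicates = 1)) {
  lattice <- seq(range[1], range[2], by = step)
  res <- growth_params_over_temperature(models, lattice, config)
  tc <- res$summary$tc_mean
  r0 <- res$summary$r0_mean
  ok <- is.finite(tc) & r0 > 0
  if (sum(ok) < 2) {
    return(function(t) rep(NA_real_, length(t)))
  }
  xs <- lattice[ok]
  ys <- tc[ok]
  function(t) stats::approx(xs, ys, xout = t, rule = 1)$y
}

#' Derived index grid (EI or GI)
#'
#' @param values numeric matrix of per-cell index values (`NA` = nodata).
#' @param kind `"EI"` or `"GI"`.
#' @param template a [climate_grid()] (or another `index_grid`) providing
#'   the georeferencing.
#' @param provenance free-text provenance note.
#' @return an object of class `index_grid`.
#' @export
index_grid <- function(values, kind = c("EI", "GI", "change"), template,
                       provenance = "") {
  kind <- match.arg(kind)
  if (kind == "EI" && any(values < 0 | values > 1, na.rm = TRUE)) {
    stop_invalid("EI values must lie in [0, 1]")
  }
  if (kind == "GI" && any(values < 0, na.rm = TRUE)) {
    stop_invalid("GI values must be >= 0")
  }
  structure(list(values = values, kind = kind, xll = template$xll,
                 yll = template$yll, cellsize = template$cellsize,
                 crs = template$crs, provenance = provenance),
            class = "index_grid")
}

# Daily mean-temperature matrix for one Julian day (internal; vectorised
# over all cells at once).
daily_mean_layer <- function(grid, wrow) {
  mn1 <- grid$tmin[, , wrow$m1]; mn2 <- grid$tmin[, , wrow$m2]
  mx1 <- grid$tmax[, , wrow$m1]; mx2 <- grid$tmax[, , wrow$m2]
  tmin_d <- (1 - wrow$w) * mn1 + wrow$w * mn2
  tmax_d <- (1 - wrow$w) * mx1 + wrow$w * mx2
  list(tmin = tmin_d, tmax = tmax_d, tmean = (tmin_d + tmax_d) / 2)
}

#' Map the establishment index over a climate grid
#'
#' Equivalent to running [establishment_index()] independently on every
#' cell's interpolated daily series, but vectorised day-by-day across the
#' whole grid.
#'
#' @inheritParams establishment_index
#' @param grid a [climate_grid()].
#' @param provenance free-text provenance recorded in the output.
#' @return an `EI` [index_grid()].
#' @export
ei_map <- function(grid, mortality_model, lethal_threshold = 0.99,
                   mode = c("mean", "extremes"), provenance = "") {
  stopifnot(inherits(grid, "climate_grid"))
  mode <- match.arg(mode)
  w <- daily_month_weights()
  dims <- dim(grid$tmin)[1:2]
  lethal <- matrix(0, dims[1], dims[2])
  for (d in seq_len(365)) {
    lay <- daily_mean_layer(grid, w[d, ])
    hit <- mortality(mortality_model, lay$tmean) >= lethal_threshold
    if (mode == "extremes") {
      hit <- hit |
        mortality(mortality_model, lay$tmin) >= lethal_threshold |
        mortality(mortality_model, lay$tmax) >= lethal_threshold
    }
    lethal <- lethal + hit
  }
  vals <- 1 - lethal / 365
  vals[grid$nodata_mask] <- NA_real_
  index_grid(vals, "EI", grid, provenance)
}

#' Map the generation index over a climate grid
#'
#' @inheritParams generation_index
#' @param grid a [climate_grid()].
#' @param provenance free-text provenance recorded in the output.
#' @return a `GI` [index_grid()].
#' @export
gi_map <- function(grid, tc_function, provenance = "") {
  stopifnot(inherits(grid, "climate_grid"))
  w <- daily_month_weights()
  dims <- dim(grid$tmin)[1:2]
  gens <- matrix(0, dims[1], dims[2])
  for (d in seq_len(365)) {
    lay <- daily_mean_layer(grid, w[d, ])
    tc <- matrix(tc_function(as.vector(lay$tmean)), dims[1], dims[2])
    g <- ifelse(is.finite(tc) & tc > 0, 365 / tc, 0)
    gens <- gens + g
  }
  vals <- gens / 365
  vals[grid$nodata_mask] <- NA_real_
  index_grid(vals, "GI", grid, provenance)
}

#' Suitability classification breaks
#'
#' Ordered EI thresholds separating the five suitability classes
#' (unsuitable / marginal / suitable / highly suitable / optimal).  Two
#' presets ship: `"strict"` = 0.3, 0.45, 0.6, 0.8 and `"lenient"` = 0.2,
#' 0.4, 0.6, 0.8.
#'
#' @param preset `"strict"` (default) or `"lenient"`; ignored when
#'   `thresholds` is given.
#' @param thresholds optional custom vector of 4 strictly increasing
#'   thresholds in `[0, 1]`.
#' @return an object of class `suitability_breaks`.
#' @export
suitability_breaks <- function(preset = c("strict", "lenient"),
                               thresholds = NULL) {
  if (is.null(thresholds)) {
    preset <- match.arg(preset)
    thresholds <- switch(preset, strict = c(0.3, 0.45, 0.6, 0.8),
                         lenient = c(0.2, 0.4, 0.6, 0.8))
  }
  if (any(diff(thresholds) <= 0) || any(thresholds < 0 | thresholds > 1)) {
    stop_invalid("thresholds must be strictly increasing within [0, 1]")
  }
  structure(list(thresholds = thresholds,
                 labels = c("unsuitable", "marginal", "suitable",
                            "highly_suitable", "optimal")),
            class = "suitability_breaks")
}

#' Classify an EI grid into suitability categories
#'
#' Intervals are half-open `[low, high)`: a cell exactly at a break joins
#' the upper class.
#'
#' @param grid an `EI` [index_grid()].
#' @param breaks a [suitability_breaks()].
#' @return a character matrix of category labels (`NA` = nodata) with the
#'   georeferencing attached as attributes.
#' @export
classify_suitability <- function(grid, breaks = suitability_breaks()) {
  stopifnot(inherits(grid, "index_grid"), inherits(breaks, "suitability_breaks"))
  if (grid$kind != "EI") stop_invalid("classification is defined for EI grids")
  idx <- findInterval(grid$values, breaks$thresholds,
                      left.open = FALSE) + 1L
  out <- matrix(breaks$labels[idx], nrow(grid$values), ncol(grid$values))
  out[is.na(grid$values)] <- NA_character_
  attr(out, "georeference") <- list(xll = grid$xll, yll = grid$yll,
                                    cellsize = grid$cellsize, crs = grid$crs)
  out
}

#' Cellwise difference of two index grids (future minus current)
#'
#' @param future,current [index_grid()] objects of the same kind, shape
#'   and georeferencing.
#' @return a `change` [index_grid()]; nodata propagates from either input.
#' @export
index_difference <- function(future, current) {
  stopifnot(inherits(future, "index_grid"), inherits(current, "index_grid"))
  if (!identical(dim(future$values), dim(current$values)) ||
      future$xll != current$xll || future$yll != current$yll ||
      future$cellsize != current$cellsize ||
      !identical(future$crs, current$crs)) {
    stop_invalid("grids are not aligned (shape or georeferencing differ)")
  }
  if (!identical(future$kind, current$kind)) {
    stop_invalid("cannot difference grids of different kinds")
  }
  index_grid(future$values - current$values, "change", future,
             provenance = paste0("difference of ", future$kind, " grids"))
}
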