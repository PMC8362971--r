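# Thermal response models: pure evaluation of every temperature- and
# age-dependent function used by the cohort simulator.  Each model is a
# light S3 object created by a constructor that validates its parameters;
# evaluation functions are vectorised over temperature and clamp their
# output to the physically meaningful codomain (rates >= 0, proportions in
# [0, 1]).  Model evaluations are intended for temperatures in [-10, 60] C;
# outside the fitted range callers must expect clamped values.

# ---- linear degree-day model -------------------------------------------

#' Linear development-rate model
#'
#' `r(T) = a + b T`, the classical degree-day model fitted to the middle,
#' linear portion of the rate-temperature relationship.  The lower
#' developmental threshold `t_min = -a/b` and the thermal constant
#' `k = 1/b` (degree-days) are derived fields.
#'
#' @param a intercept (1/day).
#' @param b slope (1/day/degree C); must be > 0 for an accepted model.
#' @return an object of class `linear_rate_model` with fields `a`, `b`,
#'   `t_min`, `k`.
#' @export
linear_rate_model <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  if (b <= 0) stop_invalid("linear rate model requires slope b > 0")
  structure(list(a = a, b = b, t_min = -a / b, k = 1 / b),
            class = "linear_rate_model")
}

#' Evaluate a linear development-rate model
#'
#' @param model a [linear_rate_model()].
#' @param t temperature (degrees C), vectorised.
#' @return development rate (1/day), clamped to `>= 0`.
#' @export
rate_linear <- function(model, t) {
  stopifnot(inherits(model, "linear_rate_model"))
  check_finite_temperature(t)
  clamp_pos(model$a + model$b * t)
}

# ---- Logan development-rate model --------------------------------------

#' Logan development-rate model
#'
#' `r(T) = gamma * (exp(rho T) - exp(rho t_max - (t_max - T)/v))`: an
#' exponential rise with temperature cut off by a high-temperature
#' boundary layer of width `v`, so that the rate is exactly zero at the
#' upper threshold `t_max` and clamped to zero above it.
#'
#' @param gamma scale (1/day).
#' @param rho rate parameter (1/degree C).
#' @param t_max upper temperature threshold (degrees C); must be > 0.
#' @param v boundary-layer width (degrees C); must be > 0.
#' @return an object of class `logan_rate_model`.
#' @export
logan_rate_model <- function(gamma, rho, t_max, v) {
  stopifnot(is.finite(gamma), is.finite(rho), is.finite(t_max), is.finite(v))
  if (v <= 0) stop_invalid("logan rate model requires boundary width v > 0")
  if (t_max <= 0) stop_invalid("logan rate model requires t_max > 0")
  structure(list(gamma = gamma, rho = rho, t_max = t_max, v = v),
            class = "logan_rate_model")
}

#' Evaluate a Logan development-rate model
#'
#' @param model a [logan_rate_model()].
#' @param t temperature (degrees C), vectorised.
#' @return development rate (1/day); exactly 0 at `t >= t_max`, clamped to
#'   `>= 0` everywhere.
#' @export
rate_logan <- function(model, t) {
  stopifnot(inherits(model, "logan_rate_model"))
  check_finite_temperature(t)
  r <- model$gamma *
    (exp(model$rho * t) -
       exp(model$rho * model$t_max - (model$t_max - t) / model$v))
  r[t >= model$t_max] <- 0
  clamp_pos(r)
}

# ---- logistic-product mortality / fecundity curves ---------------------

# Unnormalised product of an increasing and a decreasing logistic; unimodal
# (log-concave) in u with widths bl (left) and bh (right).
logistic_product <- function(u, bl, bh) {
  1 / ((1 + exp(-u / bl)) * (1 + exp(u / bh)))
}

# Location of the product's maximum relative to u = 0 (shifts away from 0
# when bl != bh) and its value there.  Used to re-centre the curve so the
# stated optimum temperature is exactly the extremum.
logistic_product_peak <- function(bl, bh) {
  opt <- stats::optimize(function(u) logistic_product(u, bl, bh),
                         interval = c(-30 * bl, 30 * bh), maximum = TRUE,
                         tol = 1e-10)
  list(offset = opt$maximum, height = opt$objective)
}

#' U-shaped immature mortality curve
#'
#' Mortality is modelled as one minus a scaled product of two logistic
#' terms, giving a smooth U with its minimum exactly at `t_opt`:
#' `m(T) = 1 - h * g(T - c) / g_max`, where `g` is the logistic product
#' with left width `b_low` and right width `b_high` and `c` re-centres the
#' extremum at `t_opt`.  `h` in (0, 1] is peak survival, so the minimum
#' mortality is `1 - h`; mortality tends to 1 at both temperature extremes.
#'
#' The derived fields `t_lethal_low` and `t_lethal_high` are the
#' temperatures at which the curve reaches `lethal_level` (mortality
#' indistinguishable from total), found by root bracketing.
#'
#' @param t_opt temperature of minimum mortality (degrees C).
#' @param b_low,b_high low- and high-side width parameters (degrees C),
#'   both > 0.
#' @param h peak survival proportion in (0, 1].
#' @param lethal_level mortality level treated as total when deriving the
#'   lethal temperatures (default 0.999).
#' @return an object of class `mortality_curve`.
#' @export
mortality_curve <- function(t_opt, b_low, b_high, h, lethal_level = 0.999) {
  stopifnot(is.finite(t_opt), is.finite(b_low), is.finite(b_high),
            is.finite(h))
  if (b_low <= 0 || b_high <= 0) {
    stop_invalid("mortality curve requires b_low > 0 and b_high > 0")
  }
  if (h <= 0 || h > 1) stop_invalid("mortality curve requires h in (0, 1]")
  pk <- logistic_product_peak(b_low, b_high)
  obj <- structure(list(t_opt = t_opt, b_low = b_low, b_high = b_high,
                        h = h, centre = t_opt - pk$offset,
                        g_max = pk$height, lethal_level = lethal_level),
                   class = "mortality_curve")
  obj$t_lethal_low <- lethal_crossing(obj, lethal_level, "low")
  obj$t_lethal_high <- lethal_crossing(obj, lethal_level, "high")
  obj
}

# Temperature where mortality first reaches `level` on the given side of
# t_opt; -Inf/Inf if the curve never gets there within +-200 C.
lethal_crossing <- function(curve, level, side = c("low", "high")) {
  side <- match.arg(side)
  f <- function(t) mortality(curve, t) - level
  lo <- if (side == "low") curve$t_opt - 200 else curve$t_opt
  hi <- if (side == "low") curve$t_opt else curve$t_opt + 200
  if (f(lo) < 0 && f(hi) < 0) return(if (side == "low") -Inf else Inf)
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-9)
  root$root
}

#' Evaluate an immature mortality curve
#'
#' @param model a [mortality_curve()].
#' @param t temperature (degrees C), vectorised.
#' @return mortality proportion in `[0, 1]`, minimised at `t_opt`.
#' @export
mortality <- function(model, t) {
  stopifnot(inherits(model, "mortality_curve"))
  check_finite_temperature(t)
  g <- logistic_product(t - model$centre, model$b_low, model$b_high)
  clamp01(1 - model$h * g / model$g_max)
}

#' Unimodal lifetime-fecundity curve
#'
#' Same logistic-product shape as [mortality_curve()], but parameterising
#' lifetime eggs per female: `f(T) = h * g(T - c)/g_max`, with maximum `h`
#' eggs exactly at `t_op` and decay to zero outside the viable oviposition
#' range.
#'
#' @param t_op temperature of maximum oviposition (degrees C).
#' @param b1,b_high low- and high-side width parameters (degrees C), > 0.
#' @param h peak lifetime fecundity (eggs per female), > 0.
#' @return an object of class `fecundity_curve`.
#' @export
fecundity_curve <- function(t_op, b1, b_high, h) {
  stopifnot(is.finite(t_op), is.finite(b1), is.finite(b_high), is.finite(h))
  if (b1 <= 0 || b_high <= 0) {
    stop_invalid("fecundity curve requires b1 > 0 and b_high > 0")
  }
  if (h <= 0) stop_invalid("fecundity curve requires peak fecundity h > 0")
  pk <- logistic_product_peak(b1, b_high)
  structure(list(t_op = t_op, b1 = b1, b_high = b_high, h = h,
                 centre = t_op - pk$offset, g_max = pk$height),
            class = "fecundity_curve")
}

#' Evaluate a lifetime-fecundity curve
#'
#' @param model a [fecundity_curve()].
#' @param t temperature (degrees C), vectorised.
#' @return expected lifetime eggs per female, `>= 0`.
#' @export
fecundity <- function(model, t) {
  stopifnot(inherits(model, "fecundity_curve"))
  check_finite_temperature(t)
  g <- logistic_product(t - model$centre, model$b1, model$b_high)
  clamp_pos(model$h * g / model$g_max)
}

# ---- oviposition-age schedule ------------------------------------------

#' Oviposition-age schedule
#'
#' Cumulative proportion of a female's lifetime eggs laid by normalised
#' adult age `x` (chronological age divided by expected longevity at the
#' rearing temperature): `F(x) = 1 - exp(-a x^b)`.
#'
#' @param a scale parameter, > 0 (dimensionless).
#' @param b shape parameter, > 0 (dimensionless).
#' @return an object of class `oviposition_age_model`.
#' @export
oviposition_age_model <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  if (a <= 0 || b <= 0) {
    stop_invalid("oviposition age model requires a > 0 and b > 0")
  }
  structure(list(a = a, b = b), class = "oviposition_age_model")
}

#' Cumulative oviposition proportion at a normalised age
#'
#' @param model an [oviposition_age_model()].
#' @param x normalised female age, `>= 0`, vectorised.
#' @return cumulative proportion of lifetime eggs laid, in `[0, 1)`.
#' @export
oviposition_cdf <- function(model, x) {
  stopifnot(inherits(model, "oviposition_age_model"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_invalid("normalised age x must be finite and >= 0")
  }
  1 - exp(-model$a * x^model$b)
}

# Quantile function of the oviposition-age schedule (inverse cdf).
oviposition_quantile <- function(model, p) {
  (-log1p(-p) / model$a)^(1 / model$b)
}

# ---- adult senescence ---------------------------------------------------

#' Ratkowsky adult senescence model
#'
#' Senescence rate (inverse expected adult longevity) as a parabola in
#' temperature: `s(T) = b (T - t_b)^2`, zero at the vertex `t_b`.
#'
#' @param b curvature (1/day/degree C squared), > 0.
#' @param t_b temperature of zero senescence (degrees C).
#' @return an object of class `senescence_model`.
#' @export
senescence_model <- function(b, t_b) {
  stopifnot(is.finite(b), is.finite(t_b))
  if (b <= 0) stop_invalid("senescence model requires curvature b > 0")
  structure(list(b = b, t_b = t_b), class = "senescence_model")
}

#' Evaluate an adult senescence model
#'
#' @param model a [senescence_model()].
#' @param t temperature (degrees C), vectorised.
#' @return senescence rate (1/day), `>= 0`.
#' @export
senescence_rate <- function(model, t) {
  stopifnot(inherits(model, "senescence_model"))
  check_finite_temperature(t)
  model$b * (t - model$t_b)^2
}

#' Expected adult longevity implied by a senescence model
#'
#' The reciprocal of the senescence rate, reported as `Inf` where the rate
#' is zero (the parabola's vertex).  Because the parabola sends expected
#' longevity to infinity near its vertex, an optional cap bounds the
#' prediction; simulation code applies the cap by default.
#'
#' @param model a [senescence_model()].
#' @param t temperature (degrees C), vectorised.
#' @param max_longevity optional upper bound (days) on the returned
#'   expectation; `Inf` disables it.
#' @return expected longevity (days).
#' @export
expected_longevity <- function(model, t, max_longevity = Inf) {
  s <- senescence_rate(model, t)
  pmin(ifelse(s > 0, 1 / s, Inf), max_longevity)
}

# ---- compiled model set -------------------------------------------------

#' Compiled thermal phenology model set
#'
#' Bundles one fitted model per demographic trait, forming the complete
#' input to the cohort simulator: development rate (nonlinear and linear),
#' the development-time distribution, immature mortality, lifetime
#' fecundity, the oviposition-age schedule and male/female senescence.
#' Adult-longevity spread distributions are optional; when absent,
#' simulated lifespans are deterministic at the model median.
#'
#' @param dev_rate a [logan_rate_model()].
#' @param dev_rate_linear a [linear_rate_model()].
#' @param dev_time_dist a [devtime_distribution()] for egg-to-adult
#'   development.
#' @param immature_mortality a [mortality_curve()].
#' @param fecundity a [fecundity_curve()].
#' @param oviposition_age an [oviposition_age_model()].
#' @param female_senescence,male_senescence [senescence_model()] objects.
#' @param female_longevity_dist,male_longevity_dist optional
#'   [devtime_distribution()] objects whose common slope sets the spread of
#'   adult lifespans.
#' @return an object of class `thermal_model_set`.
#' @export
thermal_model_set <- function(dev_rate, dev_rate_linear, dev_time_dist,
                              immature_mortality, fecundity, oviposition_age,
                              female_senescence, male_senescence,
                              female_longevity_dist = NULL,
                              male_longevity_dist = NULL) {
  stopifnot(inherits(dev_rate, "logan_rate_model"),
            inherits(dev_rate_linear, "linear_rate_model"),
            inherits(dev_time_dist, "devtime_distribution"),
            inherits(immature_mortality, "mortality_curve"),
            inherits(fecundity, "fecundity_curve"),
            inherits(oviposition_age, "oviposition_age_model"),
            inherits(female_senescence, "senescence_model"),
            inherits(male_senescence, "senescence_model"))
  if (!is.null(female_longevity_dist)) {
    stopifnot(inherits(female_longevity_dist, "devtime_distribution"))
  }
  if (!is.null(male_longevity_dist)) {
    stopifnot(inherits(male_longevity_dist, "devtime_distribution"))
  }
  structure(list(dev_rate = dev_rate,
                 dev_rate_linear = dev_rate_linear,
                 dev_time_dist = dev_time_dist,
                 immature_mortality = immature_mortality,
                 fecundity = fecundity,
                 oviposition_age = oviposition_age,
                 female_senescence = female_senescence,
                 male_senescence = male_senescence,
                 female_longevity_dist = female_longevity_dist,
                 male_longevity_dist = male_longevity_dist),
            class = "thermal_model_set")
}

#' @export
print.thermal_model_set <- function(x, ...) {
  cat("<thermal_model_set>\n")
  cat(sprintf("  development:  Logan (t_max = %.2f C), linear (t_min = %.2f C, k = %.1f DD)\n",
              x$dev_rate$t_max, x$dev_rate_linear$t_min, x$dev_rate_linear$k))
  cat(sprintf("  dev-time distribution: %s link, common slope %.2f, %d temperature groups\n",
              x$dev_time_dist$link, x$dev_time_dist$slope_b,
              length(x$dev_time_dist$intercepts)))
  cat(sprintf("  immature mortality: minimum %.3f at %.2f C\n",
              1 - x$immature_mortality$h, x$immature_mortality$t_opt))
  cat(sprintf("  fecundity: peak %.1f eggs/female at %.2f C\n",
              x$fecundity$h, x$fecundity$t_op))
  cat(sprintf("  senescence vertices: female %.2f C, male %.2f C\n",
              x$female_senescence$t_b, x$male_senescence$t_b))
  invisible(x)
}
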