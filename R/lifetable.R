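# Stochastic cohort simulation at constant temperature and the classical
# life-table machinery built on it: age-specific survivorship (lx) and
# daily female-offspring output (mx), and the population growth
# parameters rm, GRR, R0, Tc, Dt and lambda.
#
# The life table follows the female line (the standard convention): lx is
# the survivorship of female-fated eggs and mx the daughters produced per
# living female per day, so that R0 = sum(lx mx) matches the closed-form
# expectation (1 - mortality) * sex_ratio * fecundity.

#' Cohort simulation configuration
#'
#' @param temperature rearing temperature (degrees C).
#' @param n_eggs cohort size at the egg stage (default 200).
#' @param replicates number of replicate cohorts (default 3).
#' @param time_step simulation step in days (default 1).
#' @param sex_ratio proportion of eggs that are female, in (0, 1)
#'   (default 0.5).
#' @param seed RNG seed for the cohort (default 1).
#' @param max_longevity cap (days) on the expected adult longevity implied
#'   by the senescence parabola, which diverges at its vertex (default 25,
#'   just above the longest observed mean adult longevity).
#' @param dispersion negative-binomial size parameter for per-female
#'   lifetime egg totals; `Inf` (the default) gives the Poisson limit.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(temperature, n_eggs = 200, replicates = 3,
                          time_step = 1, sex_ratio = 0.5, seed = 1,
                          max_longevity = 25, dispersion = Inf) {
  stopifnot(is.finite(temperature))
  if (n_eggs < 1) stop_invalid("n_eggs must be >= 1")
  if (sex_ratio <= 0 || sex_ratio >= 1) {
    stop_invalid("sex_ratio must be strictly between 0 and 1")
  }
  if (time_step <= 0) stop_invalid("time_step must be > 0")
  structure(list(temperature = temperature, n_eggs = as.integer(n_eggs),
                 replicates = as.integer(replicates),
                 time_step = time_step, sex_ratio = sex_ratio,
                 seed = as.integer(seed), max_longevity = max_longevity,
                 dispersion = dispersion),
            class = "cohort_config")
}

# Draw per-female lifetime egg totals.
draw_egg_totals <- function(n, mu, dispersion) {
  if (n == 0) return(integer(0))
  if (mu <= 0) return(rep(0L, n))
  if (is.finite(dispersion)) {
    stats::rnbinom(n, size = dispersion, mu = mu)
  } else {
    stats::rpois(n, mu)
  }
}

# Allocate each female's egg total over her lived adult days by
# inverse-cdf sampling of the oviposition-age schedule, truncated and
# renormalised to her realised lifespan (all drawn eggs are laid).
allocate_eggs <- function(totals, lifespans, ovi, norm_scale, time_step) {
  keep <- totals > 0
  if (!any(keep)) {
    return(data.frame(idx = integer(0), adult_age = numeric(0),
                      eggs = integer(0)))
  }
  idx <- rep(which(keep), totals[keep])
  cap <- oviposition_cdf(ovi, lifespans[idx] / norm_scale)
  u <- stats::runif(length(idx)) * cap
  x <- oviposition_quantile(ovi, u)
  age <- pmin(ceiling((x * norm_scale) / time_step) * time_step,
              lifespans[idx])
  age <- pmax(age, time_step)
  agg <- stats::aggregate(list(eggs = rep(1L, length(idx))),
                          by = list(idx = idx, adult_age = age), FUN = sum)
  agg[order(agg$idx, agg$adult_age), ]
}

#' Simulate one cohort at constant temperature
#'
#' Each egg is assigned a sex, survives the immature stage with
#' probability `1 - m(T)`, and (if it survives) completes development at a
#' time drawn from the fitted development-time distribution re-centred on
#' the Logan-model median `1/r(T)`.  Adults die at ages drawn from the
#' longevity distributions around the senescence-model median, and each
#' female lays a lifetime egg total drawn around the fecundity-curve mean,
#' spread over her lived days according to the oviposition-age schedule.
#' A temperature where the development rate is zero or mortality is total
#' yields an all-dead cohort, not an error.  Fully reproducible from the
#' config seed.
#'
#' @param models a [thermal_model_set()].
#' @param config a [cohort_config()].
#' @return an object of class `cohort_records`: a list with `individuals`
#'   (one row per egg: `id`, `sex`, `survived_immature`, `dev_day`,
#'   `adult_death_day`), `eggs` (daily egg counts per female:
#'   `id`, `adult_age`, `eggs`) and the `config`.
#' @export
simulate_cohort <- function(models, config) {
  stopifnot(inherits(models, "thermal_model_set"),
            inherits(config, "cohort_config"))
  tt <- config$temperature
  step <- config$time_step
  n <- config$n_eggs
  with_local_seed(config$seed, {
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
    m <- mortality(models$immature_mortality, tt)
    r <- rate_logan(models$dev_rate, tt)
    viable <- r > 0 && m < 1
    survived <- if (viable) stats::runif(n) >= m else rep(FALSE, n)

    dev_day <- rep(NA_real_, n)
    if (r > 0) {
      raw <- sample_dev_time(models$dev_time_dist, 1 / r, n)
      dev_day <- ceiling(raw / step) * step
    }
    # immatures that die are recorded as dying at their would-be
    # development day (death during the stage, detected at emergence); if
    # development never completes (r = 0) they die in the first step.
    immature_death <- ifelse(is.na(dev_day), step, dev_day)

    adult_death <- rep(NA_real_, n)
    is_adult <- survived
    if (any(is_adult)) {
      lf <- expected_longevity(models$female_senescence, tt,
                               config$max_longevity)
      lm_ <- expected_longevity(models$male_senescence, tt,
                                config$max_longevity)
      draw_life <- function(dist, med, k) {
        if (k == 0) return(numeric(0))
        if (!is.finite(med) || med <= 0) return(rep(step, k))
        if (is.null(dist)) rep(med, k) else sample_dev_time(dist, med, k)
      }
      fem <- is_adult & sex == "F"
      mal <- is_adult & sex == "M"
      adult_death[fem] <- pmax(step, ceiling(
        draw_life(models$female_longevity_dist, lf, sum(fem)) / step) * step)
      adult_death[mal] <- pmax(step, ceiling(
        draw_life(models$male_longevity_dist, lm_, sum(mal)) / step) * step)
    }

    eggs <- data.frame(id = integer(0), adult_age = numeric(0),
                       eggs = integer(0))
    fem_ids <- which(is_adult & sex == "F")
    if (length(fem_ids)) {
      mu <- fecundity(models$fecundity, tt)
      totals <- draw_egg_totals(length(fem_ids), mu, config$dispersion)
      lf_norm <- expected_longevity(models$female_senescence, tt,
                                    config$max_longevity)
      alloc <- allocate_eggs(totals, adult_death[fem_ids],
                             models$oviposition_age, lf_norm, step)
      eggs <- data.frame(id = fem_ids[alloc$idx],
                         adult_age = alloc$adult_age,
                         eggs = alloc$eggs)
    }

    individuals <- data.frame(
      id = seq_len(n), sex = sex, survived_immature = survived,
      dev_day = ifelse(survived, dev_day, NA_real_),
      immature_death_day = ifelse(survived, NA_real_, immature_death),
      adult_death_day = adult_death)
    structure(list(individuals = individuals, eggs = eggs, config = config),
              class = "cohort_records")
  })
}

#' Build an age-indexed life-table schedule from cohort records
#'
#' Survivorship `lx` follows the female line: the fraction of female eggs
#' still alive at cohort age `x` (immature deaths are placed at their
#' would-be development day).  `mx` is daughters per living female per
#' step: daily eggs laid at cohort age `x` divided by the number of living
#' females, times the sex ratio.  A cohort without female eggs yields an
#' all-zero `mx` (R0 = 0 downstream) with `lx` taken over the whole
#' cohort.
#'
#' @param records a `cohort_records` object from [simulate_cohort()].
#' @return an object of class `life_table`: a data frame with columns
#'   `x` (age, days), `lx` and `mx`.
#' @export
build_life_table <- function(records) {
  stopifnot(inherits(records, "cohort_records"))
  ind <- records$individuals
  if (nrow(ind) == 0) stop_invalid("empty cohort records")
  cfg <- records$config
  step <- cfg$time_step

  death_age <- ifelse(ind$survived_immature,
                      ind$dev_day + ind$adult_death_day,
                      ind$immature_death_day)
  fem <- ind$sex == "F"
  line <- if (any(fem)) fem else rep(TRUE, nrow(ind))

  egg_age <- numeric(0)
  egg_n <- integer(0)
  if (nrow(records$eggs)) {
    egg_age <- ind$dev_day[records$eggs$id] + records$eggs$adult_age - step
    egg_n <- records$eggs$eggs
  }
  max_age <- max(death_age[line], if (length(egg_age)) egg_age else 0)
  x <- seq(0, max_age, by = step)

  da <- death_age[line]
  lx <- vapply(x, function(z) mean(da > z), numeric(1))

  eggs_at <- numeric(length(x))
  if (length(egg_age)) {
    tab <- tapply(egg_n, factor(egg_age, levels = x), sum)
    eggs_at <- ifelse(is.na(tab), 0, tab)
  }
  fem_death <- death_age[fem]
  fem_alive <- vapply(x, function(z) sum(fem_death > z), numeric(1))
  mx <- ifelse(fem_alive > 0, cfg$sex_ratio * eggs_at / fem_alive, 0)

  structure(data.frame(x = x, lx = lx, mx = mx),
            class = c("life_table", "data.frame"))
}

#' Population growth parameters from a life-table schedule
#'
#' Computes the gross reproductive rate `GRR = sum(mx)`, the net
#' reproductive rate `R0 = sum(lx mx)`, the mean generation time
#' `Tc = sum(x lx mx) / R0`, the intrinsic rate of increase `rm`, the
#' doubling time `Dt = ln 2 / rm` and the finite rate of increase
#' `lambda = exp(rm)`.  `rm` is obtained either by solving the
#' renewal equation `sum(exp(-rm x) lx mx) = 1` by bracketing and
#' root refinement to an absolute residual below 1e-10 (`method =
#' "lotka"`), or by the classical approximation `rm = ln(R0)/Tc`.
#'
#' @param schedule a [build_life_table()] result (or any data frame with
#'   columns `x`, `lx`, `mx`).
#' @param method `"lotka"` (default) or `"approximation"`.
#' @return an object of class `growth_parameters`: a list with elements
#'   `rm`, `grr`, `r0`, `tc`, `dt`, `lam`, `method`, `lotka_residual` and
#'   `r0_zero` (flag: reproduction absent, `rm` undefined).
#' @export
growth_parameters <- function(schedule, method = c("lotka", "approximation")) {
  method <- match.arg(method)
  stopifnot(all(c("x", "lx", "mx") %in% names(schedule)))
  x <- schedule$x
  lxmx <- schedule$lx * schedule$mx
  r0 <- sum(lxmx)
  grr <- sum(schedule$mx)
  if (r0 <= 0) {
    return(structure(list(rm = NA_real_, grr = grr, r0 = r0, tc = NA_real_,
                          dt = NA_real_, lam = NA_real_, method = method,
                          lotka_residual = NA_real_, r0_zero = TRUE),
                     class = "growth_parameters"))
  }
  tc <- sum(x * lxmx) / r0
  residual <- NA_real_
  if (method == "lotka") {
    pos <- lxmx > 0                 # drop zero terms: avoids 0 * Inf = NaN
    xp <- x[pos]
    wp <- lxmx[pos]
    f <- function(r) sum(exp(-r * xp) * wp) - 1
    lo <- -2; hi <- 2
    while (f(hi) > 0) hi <- hi * 2
    while (f(lo) < 0) lo <- lo * 2
    root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-15,
                           maxiter = 2000)
    rm <- root$root
    # bisection polish in case uniroot's interpolation stalls
    iter <- 0
    while (abs(f(rm)) >= 1e-10 && iter < 200) {
      if (f(lo) * f(rm) <= 0) hi <- rm else lo <- rm
      rm <- (lo + hi) / 2
      iter <- iter + 1
    }
    residual <- f(rm)
  } else {
    rm <- log(r0) / tc
  }
  structure(list(rm = rm, grr = grr, r0 = r0, tc = tc,
                 dt = if (rm != 0) log(2) / rm else NA_real_,
                 lam = exp(rm), method = method,
                 lotka_residual = residual, r0_zero = FALSE),
            class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat(sprintf(
    "<growth_parameters (%s)> rm = %.4f, GRR = %.2f, R0 = %.3f, Tc = %.2f d, Dt = %.2f d, lambda = %.4f\n",
    x$method, x$rm, x$grr, x$r0, x$tc, x$dt, x$lam))
  invisible(x)
}

#' Simulated growth parameters across temperatures
#'
#' Runs replicate stochastic cohorts at each temperature (with seeds
#' derived deterministically from the config seed) and summarises the
#' growth parameters as mean and standard error per temperature.
#'
#' @param models a [thermal_model_set()].
#' @param temperatures temperatures (degrees C) to simulate.
#' @param config a [cohort_config()] template; its `temperature` field is
#'   overridden per run and its seed drives the per-replicate seeds.
#' @param method passed to [growth_parameters()].
#' @return a list with `summary` (one row per temperature: mean and SE
#'   columns per parameter) and `replicates` (one row per temperature x
#'   replicate, with the seed used).
#' @export
growth_params_over_temperature <- function(models, temperatures,
                                           config = cohort_config(temperatures[1]),
                                           method = "lotka") {
  if (length(temperatures) < 1) stop_invalid("need at least one temperature")
  rows <- list()
  for (ti in seq_along(temperatures)) {
    for (rep_i in seq_len(config$replicates)) {
      cfg <- config
      cfg$temperature <- temperatures[ti]
      cfg$seed <- derive_seed(config$seed, ti, rep_i)
      rec <- simulate_cohort(models, cfg)
      gp <- growth_parameters(build_life_table(rec), method = method)
      rows[[length(rows) + 1]] <- data.frame(
        temperature = temperatures[ti], replicate = rep_i, seed = cfg$seed,
        rm = gp$rm, grr = gp$grr, r0 = gp$r0, tc = gp$tc, dt = gp$dt,
        lam = gp$lam)
    }
  }
  reps <- do.call(rbind, rows)
  pars <- c("rm", "grr", "r0", "tc", "dt", "lam")
  summ <- do.call(rbind, lapply(unique(reps$temperature), function(tt) {
    sub <- reps[reps$temperature == tt, ]
    out <- data.frame(temperature = tt)
    for (p in pars) {
      out[[paste0(p, "_mean")]] <- mean(sub[[p]])
      out[[paste0(p, "_se")]] <- std_err(sub[[p]])
    }
    out
  }))
  list(summary = summ, replicates = reps)
}
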