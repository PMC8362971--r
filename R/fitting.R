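# Model fitting: ordinary least squares for the degree-day thresholds,
# multi-start bounded Levenberg-Marquardt for the nonlinear thermal
# response families, and joint binomial fitting of the shared-slope
# development-time / longevity distributions.

#' Fit-statistics container
#'
#' @param family family name (character).
#' @param params named numeric vector of parameter estimates.
#' @param se named numeric vector of approximate standard errors (may be
#'   `NA` where the curvature is uninformative).
#' @param r_squared coefficient of determination `1 - SSE/SST` (may be
#'   negative for poor nonlinear fits).
#' @param aic information criterion used for ranking:
#'   `n log(SSE/n) + 2p` for least-squares fits, `-2 logLik + 2p` for
#'   likelihood fits.
#' @param residual_df residual degrees of freedom.
#' @param converged logical.
#' @param n_starts_used number of optimiser starts attempted.
#' @param augmented logical: whether pseudo-observations entered the fit.
#' @return an object of class `fit_result`.
#' @export
fit_result <- function(family, params, se = NULL, r_squared = NA_real_,
                       aic = NA_real_, residual_df = NA_integer_,
                       converged = FALSE, n_starts_used = NA_integer_,
                       augmented = FALSE) {
  structure(list(family = family, params = params, se = se,
                 r_squared = r_squared, aic = aic,
                 residual_df = residual_df, converged = converged,
                 n_starts_used = n_starts_used, augmented = augmented),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s>%s\n", x$family,
              if (x$converged) "" else "  (NOT converged)"))
  est <- data.frame(estimate = x$params,
                    se = if (is.null(x$se)) NA_real_ else x$se)
  print(round(est, 5))
  cat(sprintf("  R2 = %.4f, AIC = %.2f, residual df = %d\n",
              x$r_squared, x$aic, x$residual_df))
  invisible(x)
}

# ---- linear degree-day thresholds --------------------------------------

#' Fit the linear degree-day model and thermal thresholds
#'
#' Ordinary (optionally weighted) least squares of mean development rate
#' on temperature; the lower developmental threshold `t_min = -a/b` and
#' the thermal constant `k = 1/b` follow from the coefficients.
#'
#' @param temperatures numeric vector of rearing temperatures (degrees C),
#'   at least 3.
#' @param rates mean development rates (1/day) at those temperatures, > 0.
#' @param weights optional regression weights.
#' @return a list with elements `model` (a [linear_rate_model()]) and
#'   `fit` (a [fit_result()]); the fit is also attached to the model as
#'   attribute `"fit"`.
#' @export
fit_linear_thresholds <- function(temperatures, rates, weights = NULL) {
  stopifnot(length(temperatures) == length(rates))
  if (length(temperatures) < 3) {
    stop_invalid("insufficient data: need >= 3 temperatures for the linear model")
  }
  if (any(rates <= 0)) stop_invalid("development rates must be > 0")
  df <- data.frame(t = temperatures, r = rates)
  fit <- stats::lm(r ~ t, data = df, weights = weights)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0) {
    stop_invalid("no valid threshold: fitted slope b <= 0")
  }
  model <- linear_rate_model(a, b)
  n <- nrow(df)
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((df$r - mean(df$r))^2)
  res <- fit_result(
    family = "linear",
    params = c(a = a, b = b, t_min = model$t_min, k = model$k),
    se = c(a = suppressWarnings(summary(fit))$coefficients[1, 2],
           b = suppressWarnings(summary(fit))$coefficients[2, 2],
           t_min = NA, k = NA),
    r_squared = 1 - sse / sst,
    aic = n * log(sse / n) + 2 * 2,
    residual_df = n - 2L,
    converged = TRUE, n_starts_used = 1L)
  attr(model, "fit") <- res
  list(model = model, fit = res)
}

# ---- nonlinear families -------------------------------------------------

# Registry of the fit families: prediction function, parameter names,
# multi-start boxes (data-dependent), and hard bounds.  Boxes follow the
# biology: thresholds near the observed temperature range, widths of a few
# degrees, heights near the observed response ceiling.
nonlinear_family <- function(family, x, y) {
  switch(family,
    logan1 = list(
      par_names = c("gamma", "rho", "t_max", "v"),
      predict = function(p, x) {
        p[1] * (exp(p[2] * x) - exp(p[2] * p[3] - (p[3] - x) / p[4]))
      },
      build = function(p) logan_rate_model(p[1], p[2], p[3], p[4]),
      box = rbind(gamma = log10(c(1e-4, 0.2)), rho = c(0.02, 0.5),
                  t_max = c(max(x) + 0.3, 50), v = c(0.2, 20)),
      log_scale = c(TRUE, FALSE, FALSE, FALSE),
      lower = c(1e-9, 1e-3, max(x) + 0.05, 0.01),
      upper = c(10, 2, 70, 100),
      # the 4-point surface is multimodal in t_max: profile the threshold
      # over a grid and use the profile solutions as additional starts
      profile = list(index = 3,
                     grid = seq(max(x) + 0.5, max(x) + 12, by = 0.5),
                     seeds = rbind(c(0.01, 0.12, NA, 4),
                                   c(0.05, 0.20, NA, 6),
                                   c(0.002, 0.30, NA, 2)))),
    mortality_curve = list(
      par_names = c("t_opt", "b_low", "b_high", "h"),
      predict = function(p, x) mortality(mortality_curve(p[1], p[2], p[3], p[4]), x),
      build = function(p) mortality_curve(p[1], p[2], p[3], p[4]),
      box = rbind(t_opt = range(x), b_low = c(0.3, 12),
                  b_high = c(0.2, 8), h = c(0.3, 1)),
      log_scale = rep(FALSE, 4),
      lower = c(min(x) - 5, 0.05, 0.05, 0.01),
      upper = c(max(x) + 5, 50, 50, 1)),
    fecundity_curve = list(
      par_names = c("t_op", "b1", "b_high", "h"),
      predict = function(p, x) fecundity(fecundity_curve(p[1], p[2], p[3], p[4]), x),
      build = function(p) fecundity_curve(p[1], p[2], p[3], p[4]),
      box = rbind(t_op = range(x), b1 = c(0.3, 12), b_high = c(0.2, 8),
                  h = c(0.5 * max(y), 2 * max(y))),
      log_scale = rep(FALSE, 4),
      lower = c(min(x) - 5, 0.05, 0.05, 1e-3),
      upper = c(max(x) + 5, 50, 50, 10 * max(y))),
    ratkowsky = list(
      par_names = c("b", "t_b"),
      predict = function(p, x) p[1] * (x - p[2])^2,
      build = function(p) senescence_model(p[1], p[2]),
      box = rbind(b = log10(c(1e-4, 0.05)), t_b = c(min(x) - 5, max(x))),
      log_scale = c(TRUE, FALSE),
      lower = c(1e-8, -20),
      upper = c(1, 45)),
    oviposition_age = list(
      par_names = c("a", "b"),
      predict = function(p, x) 1 - exp(-p[1] * x^p[2]),
      build = function(p) oviposition_age_model(p[1], p[2]),
      box = rbind(a = c(0.05, 5), b = c(0.3, 4)),
      log_scale = c(FALSE, FALSE),
      lower = c(1e-4, 0.05),
      upper = c(50, 20)),
    stop_invalid("unknown nonlinear family '", family, "'"))
}

# Latin-hypercube starts over the family's parameter box (log-spaced where
# flagged), with a fixed local RNG stream so fitting never disturbs the
# caller's RNG state.
multi_start_grid <- function(fam, n_starts, seed) {
  k <- length(fam$par_names)
  u <- with_local_seed(seed, lhs::randomLHS(n_starts, k))
  starts <- matrix(NA_real_, n_starts, k)
  for (j in seq_len(k)) {
    lo <- fam$box[j, 1]; hi <- fam$box[j, 2]
    val <- lo + u[, j] * (hi - lo)
    if (fam$log_scale[j]) val <- 10^val
    starts[, j] <- val
  }
  colnames(starts) <- fam$par_names
  starts
}

# Solve the least-squares problem with one parameter pinned to each value
# of a profile grid; the converged profile solutions (with the parameter
# freed again) make robust starts for the full fit.
profile_starts <- function(fam, resid_fn, base_starts) {
  idx <- fam$profile$index
  out <- list()
  seeds <- fam$profile$seeds %||%
    base_starts[seq_len(min(3, nrow(base_starts))), , drop = FALSE]
  for (g in fam$profile$grid) {
    lo <- fam$lower; hi <- fam$upper
    lo[idx] <- g; hi[idx] <- g
    for (s in seq_len(nrow(seeds))) {
      st <- seeds[s, ]
      st[idx] <- g
      ans <- try(suppressWarnings(minpack.lm::nls.lm(
        par = st, fn = resid_fn, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 150))), silent = TRUE)
      if (inherits(ans, "try-error") || !ans$info %in% 1:4) next
      out[[length(out) + 1]] <- as.numeric(ans$par)
    }
  }
  if (!length(out)) return(base_starts[0, , drop = FALSE])
  m <- do.call(rbind, out)
  colnames(m) <- colnames(base_starts)
  m
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Fit a nonlinear thermal response family by multi-start least squares
#'
#' Bounded Levenberg-Marquardt minimisation from a Latin-hypercube of
#' starting points over a per-family parameter box; the best converged
#' local optimum is returned.  Optional augmentation points (for example a
#' pseudo-observation that anchors a poorly sampled part of the mortality
#' curve) enter the residual sum exactly like real observations and are
#' flagged in the result.
#'
#' @param family one of `"logan1"`, `"mortality_curve"`,
#'   `"fecundity_curve"`, `"ratkowsky"`, `"oviposition_age"`.
#' @param x predictor values (temperature, or normalised age for
#'   `"oviposition_age"`).
#' @param y observed responses.
#' @param n_starts number of optimiser starts (default 32).
#' @param seed seed for the start grid (default 1).
#' @param augmentation optional data frame with columns `x` and `y` of
#'   pseudo-observations (weighted like a typical real observation).
#' @param weights optional nonnegative regression weights (for example
#'   inverse binomial variances for mortality proportions); residuals are
#'   scaled by `sqrt(weights)`.
#' @return a list with elements `model` (the fitted S3 model object, with
#'   the fit attached as attribute `"fit"`) and `fit` (a [fit_result()]).
#' @export
fit_nonlinear <- function(family, x, y, n_starts = 32, seed = 1,
                          augmentation = NULL, weights = NULL) {
  stopifnot(length(x) == length(y), n_starts >= 1)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(x), all(weights >= 0))
  }
  augmented <- !is.null(augmentation) && nrow(augmentation) > 0
  if (augmented) {
    x <- c(x, augmentation$x)
    y <- c(y, augmentation$y)
    if (!is.null(weights)) {
      weights <- c(weights, rep(stats::median(weights),
                                nrow(augmentation)))
    }
  }
  w <- weights %||% rep(1, length(x))
  fam <- nonlinear_family(family, x, y)
  p <- length(fam$par_names)
  if (length(x) < p) {
    stop_invalid("insufficient data: ", length(x), " points for ", p,
                 " parameters")
  }
  starts <- multi_start_grid(fam, n_starts, seed)
  sw <- sqrt(w)
  resid_fn <- function(par) sw * (y - fam$predict(par, x))
  if (!is.null(fam$profile)) {
    starts <- rbind(profile_starts(fam, resid_fn, starts), starts)
  }

  best <- NULL
  diagnostics <- character(0)
  for (i in seq_len(nrow(starts))) {
    ans <- try(suppressWarnings(minpack.lm::nls.lm(
      par = starts[i, ], fn = resid_fn,
      lower = fam$lower, upper = fam$upper,
      control = minpack.lm::nls.lm.control(maxiter = 300))), silent = TRUE)
    if (inherits(ans, "try-error")) {
      diagnostics <- c(diagnostics, sprintf("start %d: %s", i,
                                            conditionMessage(attr(ans, "condition"))))
      next
    }
    if (ans$info == 5) {
      # iteration cap hit (typically a flat ridge in a scale parameter):
      # restart once from the endpoint, then accept the result
      again <- try(suppressWarnings(minpack.lm::nls.lm(
        par = ans$par, fn = resid_fn,
        lower = fam$lower, upper = fam$upper,
        control = minpack.lm::nls.lm.control(maxiter = 300))), silent = TRUE)
      if (!inherits(again, "try-error")) ans <- again
    }
    if (!ans$info %in% c(1:5)) {
      diagnostics <- c(diagnostics, sprintf("start %d: info=%d (%s)",
                                            i, ans$info, ans$message))
      next
    }
    sse <- sum(ans$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = ans, sse = sse)
  }
  if (is.null(best)) {
    stop_invalid("no start converged for family '", family, "':\n  ",
                 paste(utils::head(diagnostics, 5), collapse = "\n  "))
  }
  par <- stats::setNames(as.numeric(best$fit$par), fam$par_names)
  se <- tryCatch({
    s <- suppressWarnings(summary(best$fit))
    stats::setNames(s$coefficients[, "Std. Error"], fam$par_names)
  }, error = function(e) stats::setNames(rep(NA_real_, p), fam$par_names))
  n <- length(x)
  sse <- best$sse                               # weighted when weights given
  sst <- sum(w * (y - stats::weighted.mean(y, w))^2)
  res <- fit_result(
    family = family, params = par, se = se,
    r_squared = 1 - sse / sst,
    aic = n * log(sse / n) + 2 * p,
    residual_df = n - p,
    converged = TRUE, n_starts_used = n_starts, augmented = augmented)
  model <- fam$build(unname(par))
  attr(model, "fit") <- res
  list(model = model, fit = res)
}

# ---- shared-slope distributions ----------------------------------------

trait_times <- function(obs, trait) {
  switch(trait,
    dev_time = {
      sub <- obs$immatures[obs$immatures$survived %in% TRUE &
                             is.finite(obs$immatures$dev_days), ]
      data.frame(temperature = sub$temperature, time = sub$dev_days)
    },
    male_longevity = {
      sub <- obs$adults[obs$adults$sex == "M", ]
      data.frame(temperature = sub$temperature, time = sub$death_day)
    },
    female_longevity = {
      sub <- obs$adults[obs$adults$sex == "F", ]
      data.frame(temperature = sub$temperature, time = sub$death_day)
    },
    stop_invalid("unknown trait '", trait, "'"))
}

#' Fit a shared-slope development-time or longevity distribution
#'
#' Cumulative completion (or death) frequencies per temperature are fitted
#' jointly against ln-time with a single common slope and one intercept per
#' temperature, by maximising the binomial likelihood of the cumulative
#' counts under the chosen link.  Individuals that died as immatures are
#' excluded from the development-time distribution (they are accounted for
#' by the mortality curve).
#'
#' @param obs a [life_history()] object.
#' @param trait one of `"dev_time"`, `"male_longevity"`,
#'   `"female_longevity"`.
#' @param link `"logit"` or `"cloglog"`.
#' @return a list with elements `model` (a [devtime_distribution()]) and
#'   `fit` (a [fit_result()]).
#' @export
fit_shared_slope_distribution <- function(obs, trait = c("dev_time",
                                                         "male_longevity",
                                                         "female_longevity"),
                                          link = c("logit", "cloglog")) {
  stopifnot(inherits(obs, "life_history"))
  trait <- match.arg(trait)
  link <- match.arg(link)
  times <- trait_times(obs, trait)
  if (nrow(times) == 0) stop_invalid("no observations for trait ", trait)
  groups <- split(times$time, times$temperature)
  for (lab in names(groups)) {
    if (length(groups[[lab]]) < 2) {
      stop_invalid("degenerate fit: temperature group ", lab,
                   " has fewer than 2 individuals")
    }
    if (length(unique(groups[[lab]])) < 2) {
      stop_invalid("degenerate fit: all individuals in temperature group ",
                   lab, " share one time")
    }
  }
  cum <- do.call(rbind, lapply(names(groups), function(lab) {
    tt <- sort(groups[[lab]])
    d <- sort(unique(tt))
    data.frame(group = lab, time = d,
               k = vapply(d, function(z) sum(tt <= z), integer(1)),
               n = length(tt))
  }))
  cum$group <- factor(cum$group, levels = sort(unique(cum$group)))
  fit <- stats::glm(cbind(k, n - k) ~ 0 + group + log(time),
                    family = stats::binomial(link = link), data = cum)
  cf <- stats::coef(fit)
  slope <- unname(cf["log(time)"])
  if (!is.finite(slope) || slope <= 0) {
    stop_invalid("shared-slope fit failed: slope not positive")
  }
  intercepts <- cf[grepl("^group", names(cf))]
  names(intercepts) <- sub("^group", "", names(intercepts))
  model <- devtime_distribution(link, slope, intercepts)
  obs_freq <- cum$k / cum$n
  fit_freq <- stats::fitted(fit)
  sse <- sum((obs_freq - fit_freq)^2)
  sst <- sum((obs_freq - mean(obs_freq))^2)
  p <- length(cf)
  res <- fit_result(
    family = paste0("shared_slope_", link),
    params = c(slope_b = slope, intercepts),
    se = summary(fit)$coefficients[, 2][c(length(cf), seq_len(p - 1))],
    r_squared = 1 - sse / sst,
    aic = stats::AIC(fit),
    residual_df = fit$df.residual,
    converged = fit$converged,
    n_starts_used = 1L)
  attr(model, "fit") <- res
  list(model = model, fit = res)
}

# ---- model selection ----------------------------------------------------

#' Rank candidate fits by information criterion
#'
#' Converged candidates sorted by ascending AIC; ties (|dAIC| < 1e-6)
#' broken by higher R-squared.
#'
#' @param candidates a list of [fit_result()] objects (or of lists with a
#'   `fit` element, as returned by the fitting functions).
#' @return the ranked list of `fit_result` objects.
#' @export
select_best_model <- function(candidates) {
  fits <- lapply(candidates, function(c) {
    if (inherits(c, "fit_result")) c else c$fit
  })
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) {
    stop_invalid("no converged candidate models to rank")
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  # round AIC to the tie tolerance so order() applies the R2 tiebreak
  fits[order(round(aic / 1e-6) * 1e-6, -r2)]
}
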