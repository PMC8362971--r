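# Model fitting: threshold recovery, multi-start nonlinear least squares,
# shared-slope distribution fitting and AIC-based selection.

test_that("linear thresholds recover a noiseless degree-day model exactly", {
  tt <- c(15, 20, 25, 30)
  rates <- 0.003 * (tt - 10)
  fit <- fit_linear_thresholds(tt, rates)
  expect_equal(fit$model$t_min, 10, tolerance = 1e-10)
  expect_equal(fit$model$k, 1 / 0.003, tolerance = 1e-10)
  expect_equal(fit$model$b, 0.003, tolerance = 1e-10)
  expect_equal(fit$fit$r_squared, 1, tolerance = 1e-12)
})

test_that("linear thresholds on the reference mean rates match the hand OLS", {
  r <- reference_rates()
  fit <- fit_linear_thresholds(r$temperature, r$rate)
  # closed-form OLS oracle for these four points: t_min 9.6865, k 332.70
  expect_equal(fit$model$t_min, 9.6865, tolerance = 1e-4)
  expect_equal(fit$model$k, 332.695, tolerance = 1e-4)
  expect_lt(abs(fit$model$t_min - 10.0), 0.5)
  expect_lt(abs(fit$model$k - 333.33) / 333.33, 0.02)
})

test_that("linear threshold preconditions are enforced", {
  expect_error(fit_linear_thresholds(c(15, 20), c(0.01, 0.02)),
               "insufficient")
  expect_error(fit_linear_thresholds(c(15, 20, 25), c(0.03, 0.02, 0.01)),
               "threshold")
})

test_that("multi-start Logan fit recovers noiseless truth within 1%", {
  truth <- logan_rate_model(gamma = 0.003, rho = 0.15, t_max = 34, v = 4)
  tt <- c(15, 18, 21, 24, 27, 30, 32, 33.5)
  fit <- fit_nonlinear("logan1", tt, rate_logan(truth, tt), seed = 3)
  expect_equal(fit$model$t_max, 34, tolerance = 0.01)
  expect_equal(fit$model$rho, 0.15, tolerance = 0.01)
  expect_equal(fit$model$gamma, 0.003, tolerance = 0.01)
  expect_equal(fit$model$v, 4, tolerance = 0.01)
})

test_that("Logan fit to the four reference rates finds the upper threshold", {
  r <- reference_rates()
  fit <- fit_nonlinear("logan1", r$temperature, r$rate, seed = 1)
  expect_lt(abs(fit$model$t_max - 33.69), 1.0)
  expect_true(fit$fit$converged)
  expect_gt(fit$fit$r_squared, 0.95)
})

test_that("nonlinear fits recover each family from noiseless data", {
  tt <- c(12, 15, 18, 21, 24, 27, 30, 32, 34)
  m_truth <- mortality_curve(28, 4.5, 0.6, 0.87)
  fit_m <- fit_nonlinear("mortality_curve", tt, mortality(m_truth, tt),
                         seed = 2)
  expect_equal(fit_m$model$t_opt, 28, tolerance = 0.05)
  expect_equal(fit_m$model$h, 0.87, tolerance = 0.01)

  f_truth <- fecundity_curve(28, 3.8, 1.2, 220)
  fit_f <- fit_nonlinear("fecundity_curve", tt, fecundity(f_truth, tt),
                         seed = 2)
  expect_equal(fit_f$model$t_op, 28, tolerance = 0.05)
  expect_equal(fit_f$model$h, 220, tolerance = 0.01 * 220)

  s_truth <- senescence_model(0.0031, 21.12)
  fit_s <- fit_nonlinear("ratkowsky", tt, senescence_rate(s_truth, tt),
                         seed = 2)
  expect_equal(fit_s$model$b, 0.0031, tolerance = 0.0031 * 0.01)
  expect_equal(fit_s$model$t_b, 21.12, tolerance = 0.01)

  ov_truth <- oviposition_age_model(0.73, 1.35)
  x <- seq(0.1, 3, by = 0.2)
  fit_o <- fit_nonlinear("oviposition_age", x, oviposition_cdf(ov_truth, x),
                         seed = 2)
  expect_equal(fit_o$model$a, 0.73, tolerance = 0.73 * 0.01)
  expect_equal(fit_o$model$b, 1.35, tolerance = 1.35 * 0.01)
})

test_that("thresholds are recovered within 1 C under 5% noise most of the time", {
  # linear: 100 seeded replicates, n = 50 rate measurements per temperature
  tt_lin <- rep(c(15, 20, 25, 30), each = 50)
  hit <- 0
  for (i in 1:100) {
    set.seed(1000 + i)
    rates <- 0.003 * (tt_lin - 10) * (1 + stats::rnorm(length(tt_lin), 0, 0.05))
    fit <- fit_linear_thresholds(tt_lin, rates)
    if (abs(fit$model$t_min - 10) < 1) hit <- hit + 1
  }
  expect_gte(hit, 90)

  # Logan t_max and mortality t_opt: 50 seeded replicates on mean responses
  # over a 9-point design with 5% multiplicative noise (n = 50 per
  # temperature behind each mean => sd 0.05/sqrt(50) on the mean)
  tt <- c(15, 18, 21, 24, 27, 30, 31.5, 32.5, 33.5)
  lg_truth <- logan_rate_model(0.003, 0.15, 34, 4)
  mc_truth <- mortality_curve(28, 4.5, 0.6, 0.87)
  hit_tmax <- 0
  hit_topt <- 0
  for (i in 1:50) {
    set.seed(2000 + i)
    noise <- function(y) y * (1 + stats::rnorm(length(y), 0, 0.05 / sqrt(50)))
    fl <- fit_nonlinear("logan1", tt, noise(rate_logan(lg_truth, tt)),
                        n_starts = 12, seed = i)
    if (abs(fl$model$t_max - 34) < 1) hit_tmax <- hit_tmax + 1
    fm <- fit_nonlinear("mortality_curve", tt,
                        pmin(1, noise(mortality(mc_truth, tt))),
                        n_starts = 12, seed = i)
    if (abs(fm$model$t_opt - 28) < 1) hit_topt <- hit_topt + 1
  }
  expect_gte(hit_tmax / 50, 0.9)
  expect_gte(hit_topt / 50, 0.9)
})

test_that("augmentation points enter the residual like observations", {
  tt <- c(15, 20, 25, 30, 35)
  mc_truth <- mortality_curve(28, 4.5, 0.6, 0.87)
  y <- mortality(mc_truth, tt)
  plain <- fit_nonlinear("mortality_curve", tt, y, seed = 4)
  aug <- fit_nonlinear("mortality_curve", tt, y, seed = 4,
                       augmentation = data.frame(x = 23, y = 0.5))
  expect_false(plain$fit$augmented)
  expect_true(aug$fit$augmented)
  expect_equal(aug$fit$residual_df, plain$fit$residual_df + 1)
  # the pseudo-point pulls the curve towards 0.5 at 23 C
  expect_lt(abs(mortality(aug$model, 23) - 0.5),
            abs(mortality(plain$model, 23) - 0.5))
})

# -- shared-slope distributions ------------------------------------------

make_devtime_obs <- function(slope, intercepts, n_per_group, seed) {
  dist <- devtime_distribution("logit", slope)
  set.seed(seed)
  groups <- lapply(names(intercepts), function(lab) {
    med <- exp(-intercepts[[lab]] / slope)
    data.frame(temperature = as.numeric(lab),
               id = seq_len(n_per_group),
               survived = TRUE,
               dev_days = ceiling(sample_dev_time(dist, med, n_per_group)))
  })
  life_history(immatures = do.call(rbind, groups))
}

test_that("shared-slope fitting recovers slope and medians", {
  obs <- make_devtime_obs(15, c(`15` = -60, `25` = -45), 200, seed = 7)
  fit <- fit_shared_slope_distribution(obs, "dev_time", "logit")
  expect_equal(fit$model$slope_b, 15, tolerance = 0.10)
  expect_equal(devtime_median(fit$model, "15"), exp(60 / 15),
               tolerance = 0.03)
  expect_equal(devtime_median(fit$model, "25"), exp(45 / 15),
               tolerance = 0.03)
})

test_that("shared-slope fitting is invariant to group relabelling", {
  obs <- make_devtime_obs(15, c(`15` = -60, `25` = -45), 80, seed = 9)
  shuffled <- life_history(immatures = obs$immatures[rev(seq_len(
    nrow(obs$immatures))), ])
  f1 <- fit_shared_slope_distribution(obs, "dev_time")
  f2 <- fit_shared_slope_distribution(shuffled, "dev_time")
  expect_equal(f1$model$slope_b, f2$model$slope_b, tolerance = 1e-10)
  expect_equal(f1$model$intercepts, f2$model$intercepts, tolerance = 1e-10)
})

test_that("degenerate distribution groups are rejected by name", {
  one <- life_history(immatures = data.frame(
    temperature = c(15, 15, 20), id = 1:3, survived = TRUE,
    dev_days = c(60, 65, 30)))
  expect_error(fit_shared_slope_distribution(one, "dev_time"), "20")
  same <- life_history(immatures = data.frame(
    temperature = rep(c(15, 20), each = 3), id = 1:6, survived = TRUE,
    dev_days = c(60, 61, 62, 30, 30, 30)))
  expect_error(fit_shared_slope_distribution(same, "dev_time"), "20")
})

# -- selection ------------------------------------------------------------

test_that("model selection ranks by AIC with an R-squared tiebreak", {
  f1 <- fit_result("a", c(p = 1), aic = 10, r_squared = 0.8, converged = TRUE)
  f2 <- fit_result("b", c(p = 1), aic = 20, r_squared = 0.99, converged = TRUE)
  expect_identical(select_best_model(list(f2, f1))[[1]]$family, "a")
  t1 <- fit_result("x", c(p = 1), aic = 5, r_squared = 0.95, converged = TRUE)
  t2 <- fit_result("y", c(p = 1), aic = 5, r_squared = 0.99, converged = TRUE)
  expect_identical(select_best_model(list(t1, t2))[[1]]$family, "y")
  bad <- fit_result("z", c(p = 1), aic = 1, r_squared = 1, converged = FALSE)
  expect_error(select_best_model(list(bad)), "converged")
})

test_that("AIC penalises superfluous parameters on linear-regime data", {
  # rates generated in the linear regime: the 2-parameter linear model
  # must out-rank the 4-parameter Logan fit once the AIC penalty applies
  tt <- c(14, 16, 18, 20, 22, 24)
  set.seed(31)
  rates <- 0.003 * (tt - 10) + stats::rnorm(length(tt), 0, 3e-4)
  lin <- fit_linear_thresholds(tt, rates)
  logan <- fit_nonlinear("logan1", tt, rates, seed = 5)
  ranked <- select_best_model(list(logan, lin))
  expect_identical(ranked[[1]]$family, "linear")
  expect_lt(lin$fit$aic, logan$fit$aic)
})
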