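# Evaluation contracts of the thermal response models: known values,
# clamping, extremum placement, median identities and archive round-trips.

test_that("linear rate model evaluates and clamps as a degree-day model", {
  m <- linear_rate_model(a = -0.03, b = 0.003)
  expect_equal(m$t_min, 10)
  expect_equal(m$k, 1 / 0.003)
  expect_equal(rate_linear(m, 10), 0)            # vanishes at the threshold
  expect_equal(rate_linear(m, 25), 0.045)
  expect_equal(rate_linear(m, 5), 0)             # clamped below threshold
  expect_error(rate_linear(m, NaN), "finite")
  expect_error(linear_rate_model(0.1, -0.01), "b > 0")
})

test_that("Logan rate is zero at the upper threshold and positive below", {
  m <- logan_rate_model(gamma = 0.003, rho = 0.15, t_max = 34, v = 4)
  expect_equal(rate_logan(m, 34), 0)
  expect_equal(rate_logan(m, 39), 0)             # clamped above threshold
  expect_true(all(rate_logan(m, seq(0, 33.9, by = 0.1)) > 0))
  # the reference fit approximately interpolates the observed rate at 25 C
  expect_equal(rate_logan(truth_models$dev_rate, 25), 1 / 19.75,
               tolerance = 0.02)
  expect_error(logan_rate_model(0.003, 0.15, 34, -1), "v > 0")
})

test_that("Logan zero-at-threshold holds across a grid of accepted models", {
  # accepted thermal-performance fits have rho * v < 1 (the boundary-layer
  # decay outruns the exponential rise, so the rate stays positive up to
  # the threshold)
  cases <- expand.grid(rho = c(0.08, 0.18), v = c(1, 4),
                       tmax = c(30, 33.69, 38))
  for (k in seq_len(nrow(cases))) {
    m <- logan_rate_model(0.01, cases$rho[k], cases$tmax[k], cases$v[k])
    expect_equal(rate_logan(m, m$t_max), 0)
    expect_gt(rate_logan(m, m$t_max - 0.5), 0)
  }
})

test_that("mortality curve is a U with its minimum exactly at t_opt", {
  m <- truth_models$immature_mortality
  tt <- seq(-10, 60, by = 0.25)
  mt <- mortality(m, tt)
  expect_true(all(mt >= 0 & mt <= 1))
  # global minimum at t_opt, equal to 1 - h
  expect_equal(mortality(m, m$t_opt), 1 - m$h, tolerance = 1e-9)
  expect_true(all(mt >= mortality(m, m$t_opt) - 1e-12))
  # nonincreasing below t_opt, nondecreasing above
  below <- mt[tt <= m$t_opt]
  above <- mt[tt >= m$t_opt]
  expect_true(all(diff(below) <= 1e-12))
  expect_true(all(diff(above) >= -1e-12))
  # effectively total mortality outside the viable range (the smooth
  # logistic shoulder reaches ~0.97 at 10 C while keeping development
  # measurable at 15 C; the high side is much steeper)
  expect_gt(mortality(m, 10), 0.95)
  expect_gt(mortality(m, 5), 0.99)
  expect_gt(mortality(m, 34), 0.99)
  expect_true(is.finite(m$t_lethal_low) && m$t_lethal_low < m$t_opt)
  expect_true(is.finite(m$t_lethal_high) && m$t_lethal_high > m$t_opt)
  expect_equal(mortality(m, m$t_lethal_low), m$lethal_level, tolerance = 1e-6)
})

test_that("asymmetric widths still place the mortality minimum at t_opt", {
  m <- mortality_curve(t_opt = 26, b_low = 6, b_high = 0.7, h = 0.9)
  tt <- seq(5, 40, by = 0.01)
  expect_equal(tt[which.min(mortality(m, tt))], 26, tolerance = 0.02)
})

test_that("fecundity curve is unimodal with its peak at t_op", {
  f <- truth_models$fecundity
  tt <- seq(-10, 60, by = 0.25)
  ft <- fecundity(f, tt)
  expect_true(all(ft >= 0))
  expect_equal(fecundity(f, f$t_op), f$h, tolerance = 1e-9)
  expect_equal(tt[which.max(ft)], f$t_op, tolerance = 0.3)
  expect_lt(fecundity(f, 45), 0.5)               # outside the viable range
})

test_that("oviposition cdf saturates from zero monotonically", {
  ov <- oviposition_age_model(a = 0.73, b = 1.35)
  expect_equal(oviposition_cdf(ov, 0), 0)
  expect_equal(oviposition_cdf(ov, 1), 1 - exp(-0.73))
  expect_gt(oviposition_cdf(ov, 50), 1 - 1e-9)   # saturation
  x <- seq(0, 5, by = 0.05)
  expect_true(all(diff(oviposition_cdf(ov, x)) > 0))
  expect_error(oviposition_cdf(ov, -0.1), ">= 0")
})

test_that("senescence parabola vanishes at its vertex and gives longevity", {
  s <- senescence_model(b = 0.0031, t_b = 21.12)
  expect_equal(senescence_rate(s, 21.12), 0)
  expect_equal(senescence_rate(s, 35), 0.0031 * (35 - 21.12)^2)
  expect_equal(expected_longevity(s, 21.12), Inf)
  expect_equal(expected_longevity(s, 21.12, max_longevity = 25), 25)
  sm <- senescence_model(b = 0.0022, t_b = 20.61)
  expect_equal(senescence_rate(sm, 20.61), 0)
  # longevity shrinks as |T - t_b| grows
  expect_gt(expected_longevity(s, 23), expected_longevity(s, 30))
})

test_that("devtime cdf honours the link and the logit median identity", {
  d <- devtime_distribution("logit", 15.56,
                            c(`15` = -65.67, `30` = -43.63))
  med15 <- exp(65.67 / 15.56)
  expect_equal(devtime_cdf(d, "15", med15), 0.5, tolerance = 1e-9)
  expect_equal(devtime_median(d, "15"), med15, tolerance = 1e-9)
  # fitted 30 C group has its median near the reported mean dev time
  med30 <- exp(43.63 / 15.56)     # 16.51 d, vs reported mean 17.24 d
  expect_equal(devtime_median(d, "30"), med30, tolerance = 1e-9)
  expect_equal(devtime_cdf(d, "30", med30), 0.5, tolerance = 1e-9)
  expect_true(all(diff(devtime_cdf(d, "15", seq(30, 120, 1))) > 0))
  expect_error(devtime_cdf(d, "99", 10), "99")
  cll <- devtime_distribution("cloglog", 1.49, c(`15` = -4.78))
  expect_equal(devtime_cdf(cll, "15", 1e9), 1, tolerance = 1e-6)
})

test_that("sampled development times preserve the target median and shape", {
  d <- devtime_distribution("logit", 15.56)
  expect_equal(sample_dev_time(d, 20, p = 0.5), 20)   # median identity
  set.seed(42)
  draws <- sample_dev_time(d, 19.75, n = 1e5)
  expect_true(all(draws > 0))
  expect_equal(median(draws), 19.75, tolerance = 0.1 / 19.75)
  # an (almost) infinite slope degenerates to a point mass
  tight <- devtime_distribution("logit", 1e9)
  set.seed(1)
  expect_equal(range(sample_dev_time(tight, 20, n = 100)), c(20, 20),
               tolerance = 1e-6)
  cll <- devtime_distribution("cloglog", 1.49)
  expect_equal(sample_dev_time(cll, 12, p = 0.5), 12, tolerance = 1e-12)
})

test_that("model archive JSON round-trip is lossless", {
  tmp <- tempfile(fileext = ".json")
  write_model_archive(truth_models, tmp)
  back <- read_model_archive(tmp)
  expect_s3_class(back, "thermal_model_set")
  for (slot in c("dev_rate", "dev_rate_linear", "immature_mortality",
                 "fecundity", "oviposition_age", "female_senescence",
                 "male_senescence")) {
    orig <- truth_models[[slot]]
    got <- back[[slot]]
    for (f in names(orig)) {
      if (is.numeric(orig[[f]])) {
        expect_equal(got[[f]], orig[[f]], tolerance = 1e-12)
      }
    }
  }
  expect_equal(back$dev_time_dist$intercepts,
               truth_models$dev_time_dist$intercepts, tolerance = 1e-12)
  expect_identical(back$male_longevity_dist$link, "cloglog")
  unlink(tmp)
})

test_that("clamped outputs respect their codomains over [-10, 60]", {
  tt <- seq(-10, 60, by = 0.5)
  expect_true(all(rate_linear(truth_models$dev_rate_linear, tt) >= 0))
  expect_true(all(rate_logan(truth_models$dev_rate, tt) >= 0))
  mt <- mortality(truth_models$immature_mortality, tt)
  expect_true(all(mt >= 0 & mt <= 1))
  expect_true(all(fecundity(truth_models$fecundity, tt) >= 0))
  expect_true(all(senescence_rate(truth_models$female_senescence, tt) >= 0))
})
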