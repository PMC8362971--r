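# Spatial indices: daily interpolation, EI/GI arithmetic, classification,
# grid differencing and ASCII raster round-trips.

constant_grid <- function(tmean, nrow = 3, ncol = 3, diurnal = 0) {
  generate_climate_grid("constant", nrow, ncol, tmean = tmean,
                        diurnal_range = diurnal)
}

test_that("constant climate interpolates to a constant daily series", {
  g <- constant_grid(20)
  s <- interpolate_daily(g, 1, 1)
  expect_equal(nrow(s), 365)
  expect_equal(s$tmean, rep(20, 365))
  expect_equal(s$tmin, rep(20, 365))
  expect_equal(s$tmax, rep(20, 365))
})

test_that("mid-month days take exactly the monthly layer value", {
  tmin <- array(rep(1:12, each = 4), c(2, 2, 12))
  tmax <- tmin + 10
  g <- climate_grid(tmin, tmax)
  s <- interpolate_daily(g, 1, 1)
  # January's midpoint (day 16, centre 15.5) carries January's value
  expect_equal(s$tmin[16], 1)
  # March: 31+28+15.5 = 74.5 -> day 75
  expect_equal(s$tmin[75], 3)
  expect_equal(s$tmax[75], 13)
})

test_that("sinusoidal climate is reconstructed within 0.5 degrees", {
  amp <- 5; mean_t <- 18
  g <- generate_climate_grid("seasonal-sinusoid", 2, 2, tmean = mean_t,
                             diurnal_range = 0, amplitude = amp,
                             peak_month = 1)
  s <- interpolate_daily(g, 1, 1)
  # generating sinusoid, evaluated at daily resolution (month midpoints
  # anchor month 1 at day centre 15.5)
  truth <- mean_t + amp * cos(2 * pi * ((s$day - 0.5) - 15.5) / 365)
  expect_lt(max(abs(s$tmean - truth)), 0.5)
})

test_that("EI is 1 in benign climate, 0 in lethal climate, else arithmetic", {
  m <- truth_models$immature_mortality
  expect_equal(establishment_index(rep(20, 365), m), 1)
  expect_equal(establishment_index(rep(5, 365), m), 0)
  series <- c(rep(5, 100), rep(20, 265))
  expect_equal(establishment_index(series, m), 1 - 100 / 365)
})

test_that("EI is monotone in the lethal threshold's strictness", {
  m <- truth_models$immature_mortality
  series <- seq(8, 30, length.out = 365)
  eis <- vapply(c(0.8, 0.9, 0.95, 0.99, 0.999),
                function(th) establishment_index(series, m, th), numeric(1))
  expect_true(all(diff(eis) >= 0))  # stricter (lower) threshold => lower EI
})

test_that("the extremes mode can only flag more days lethal", {
  m <- truth_models$immature_mortality
  g <- generate_climate_grid("constant", 1, 1, tmean = 12, diurnal_range = 8)
  s <- interpolate_daily(g, 1, 1)
  expect_lte(establishment_index(s, m, mode = "extremes"),
             establishment_index(s, m, mode = "mean"))
})

test_that("GI is the closed form 365/Tc at constant temperature", {
  tc_fun <- function(t) rep(36.5, length(t))
  expect_equal(generation_index(rep(22, 365), tc_fun), 10)
  tc27 <- function(t) rep(25.796, length(t))
  expect_equal(generation_index(rep(27, 365), tc27), 365 / 25.796)
  # days outside the viable range contribute zero generations
  tc_na <- function(t) ifelse(t > 15, 36.5, NA_real_)
  expect_equal(generation_index(rep(10, 365), tc_na), 0)
})

test_that("grid maps equal independent per-cell computations", {
  g <- generate_climate_grid("latitudinal-gradient", 5, 2,
                             tmean = c(5, 30), diurnal_range = 4)
  m <- truth_models$immature_mortality
  ei <- ei_map(g, m)
  tc_fun <- function(t) ifelse(t >= 12 & t <= 33, 30, NA_real_)
  gi <- gi_map(g, tc_fun)
  for (i in 1:5) {
    for (j in 1:2) {
      s <- interpolate_daily(g, i, j)
      expect_equal(ei$values[i, j], establishment_index(s$tmean, m))
      expect_equal(gi$values[i, j], generation_index(s$tmean, tc_fun))
    }
  }
  # EI rises along the cold-to-warm gradient up to the viable plateau
  expect_true(all(diff(ei$values[, 1]) >= 0))
  expect_equal(ei$values[1, 1], 0)   # 5 C rows: every day lethal
  expect_equal(ei$values[5, 1], 1)   # 30 C rows: no lethal days
})

test_that("constant-temperature grids give EI in {0,1} and exact GI", {
  m <- truth_models$immature_mortality
  for (tt in c(5, 20, 28)) {
    g <- constant_grid(tt)
    ei <- ei_map(g, m)
    expect_true(all(ei$values %in% c(0, 1)))
  }
  tc_fun <- function(t) rep(25, length(t))
  gi <- gi_map(constant_grid(24), tc_fun)
  expect_equal(as.vector(gi$values), rep(365 / 25, 9))
})

test_that("classification uses half-open intervals with upper assignment", {
  g <- constant_grid(20)
  vals <- matrix(c(0.85, 0.29, 0.3, 0.45, 0.6, 0.8, 0.5, NA, 0), 3, 3)
  ig <- index_grid(vals, "EI", g)
  cls <- classify_suitability(ig, suitability_breaks("strict"))
  expect_equal(cls[1, 1], "optimal")          # > 0.8
  expect_equal(cls[2, 1], "unsuitable")       # < 0.3
  expect_equal(cls[3, 1], "marginal")         # exactly 0.3 -> upper class
  expect_equal(cls[1, 2], "suitable")         # exactly 0.45
  expect_equal(cls[2, 2], "highly_suitable")  # exactly 0.6
  expect_equal(cls[3, 2], "optimal")          # exactly 0.8
  expect_true(is.na(cls[2, 3]))
  expect_error(suitability_breaks(thresholds = c(0.4, 0.3, 0.6, 0.8)),
               "increasing")
})

test_that("index differencing subtracts cellwise and guards alignment", {
  g <- constant_grid(20)
  a <- index_grid(matrix(0.7, 3, 3), "EI", g)
  b <- index_grid(matrix(0.9, 3, 3), "EI", g)
  d <- index_difference(b, a)
  expect_equal(d$values, matrix(0.2, 3, 3))
  same <- index_difference(a, a)
  expect_true(all(same$values == 0))
  withna <- index_grid(matrix(c(0.5, NA, rep(0.5, 7)), 3, 3), "EI", g)
  dn <- index_difference(withna, a)
  expect_true(is.na(dn$values[2, 1]))
  g2 <- generate_climate_grid("constant", 3, 3, tmean = 20, xll = 5)
  c2 <- index_grid(matrix(0.7, 3, 3), "EI", g2)
  expect_error(index_difference(c2, a), "align")
})

test_that("ASCII grid round-trip preserves values and georeferencing", {
  m <- matrix(c(1.5, -2.25, NA, 4, 0, 7.125), 2, 3)
  tmp <- tempfile(fileext = ".asc")
  write_ascii_grid(m, tmp, xll = -10.5, yll = 3.25, cellsize = 0.5)
  back <- read_ascii_grid(tmp)
  expect_equal(back$values, m)
  expect_equal(back$xll, -10.5)
  expect_equal(back$yll, 3.25)
  expect_equal(back$cellsize, 0.5)
  unlink(tmp)
})

test_that("climate stacks survive a directory round-trip with georeferencing", {
  g <- generate_climate_grid("seasonal-sinusoid", 3, 4, tmean = 15,
                             diurnal_range = 6, amplitude = 5,
                             xll = 30, yll = -2, cellsize = 0.25)
  dir <- tempfile()
  write_climate_grid(g, dir)
  back <- read_climate_grid(dir)
  expect_equal(back$tmin, g$tmin)
  expect_equal(back$tmax, g$tmax)
  expect_equal(back$xll, g$xll)
  expect_equal(back$yll, g$yll)
  expect_equal(back$cellsize, g$cellsize)
  # derived index grids carry the input georeferencing unchanged
  ei <- ei_map(back, truth_models$immature_mortality)
  expect_equal(ei$xll, 30)
  expect_equal(ei$yll, -2)
  expect_equal(ei$cellsize, 0.25)
  unlink(dir, recursive = TRUE)
})

test_that("climate grid construction rejects inconsistent stacks", {
  tmin <- array(20, c(2, 2, 12)); tmax <- array(18, c(2, 2, 12))
  expect_error(climate_grid(tmin, tmax), "tmin exceeds tmax")
  expect_error(climate_grid(array(1, c(2, 2, 6)), array(2, c(2, 2, 6))),
               "12")
})
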