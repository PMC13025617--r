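toy_pair <- function(...) simulate_toy_calibration_curve(...)

test_that("curve files parse, interpolate linearly and reject bad grids", {
  path <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# header", "0,100,10", "10,200,20", "30,400,20"), path)
  cv <- read_curve_14c(path, step = 5)
  expect_equal(cv$cal_bp, c(0, 5, 10, 15, 20, 25, 30))
  expect_equal(cv$mu, c(100, 150, 200, 250, 300, 350, 400))  # hand interpolation
  expect_equal(cv$sigma[1:3], c(10, 15, 20))
  # knot values exact
  expect_equal(cv$mu[cv$cal_bp == 10], 200)

  bad <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("0,100,10", "0,110,10", "20,200,10"), bad)
  expect_error(read_curve_14c(bad), "not monotone")
  short <- withr::local_tempfile(fileext = ".14c")
  writeLines("0,100,10", short)
  expect_error(read_curve_14c(short), ">= 2 rows")
})

test_that("toy curves round-trip through the .14c format", {
  tc <- toy_pair(slope = 1.2, wiggle_amp = 2, reservoir_offset = 300)
  path <- withr::local_tempfile(fileext = ".14c")
  write_curve_14c(tc$marine, path)
  back <- read_curve_14c(path, step = 5)
  expect_equal(back$cal_bp, tc$marine$cal_bp)
  expect_equal(back$mu, tc$marine$mu, tolerance = 1e-6)
  expect_equal(back$sigma, tc$marine$sigma, tolerance = 1e-6)
})

test_that("reservoir offsets shift means and add errors in quadrature", {
  cv <- cal_curve(seq(0, 100, 5), rep(1000, 21), rep(20, 21))
  same <- apply_reservoir(cv, 0, 0)
  expect_equal(same$mu, cv$mu)
  expect_equal(same$sigma, cv$sigma)
  shifted <- apply_reservoir(cv, -140, 35)
  expect_equal(shifted$mu, rep(860, 21))
  expect_equal(shifted$sigma, rep(sqrt(400 + 1225), 21))
  expect_equal(shifted$sigma[1], 40.311, tolerance = 1e-3)
  # composition law: two applications = one with summed means, rss'd sds
  two <- apply_reservoir(apply_reservoir(cv, -100, 30), -40, 18)
  one <- apply_reservoir(cv, -140, sqrt(30^2 + 18^2))
  expect_equal(two$mu, one$mu)
  expect_equal(two$sigma, one$sigma)
})

test_that("curve mixing honours boundaries and the diet-uncertainty term", {
  grid <- seq(0, 100, 5)
  terr <- cal_curve(grid, rep(1000, 21), rep(20, 21))
  mar <- cal_curve(grid, rep(1500, 21), rep(20, 21))
  expect_equal(mix_curves(terr, mar, 0, 0), terr)
  expect_equal(mix_curves(terr, mar, 1, 0), mar)
  mixed <- mix_curves(terr, mar, 0.5, 0.1)
  expect_equal(mixed$mu, rep(1250, 21))
  expect_equal(mixed$sigma, rep(sqrt(100 + 100 + 2500), 21))
  expect_equal(mixed$sigma[1], 51.96, tolerance = 1e-3)
  off_grid <- cal_curve(grid + 1, mar$mu, mar$sigma)
  expect_error(mix_curves(terr, off_grid, 0.5), "common calendar grid")
  expect_error(mix_curves(terr, mar, 1.5), "marine_fraction")
})

test_that("calibration on a linear curve reproduces the Gaussian closed form", {
  tc <- toy_pair(slope = 1, wiggle_amp = 0, sigma_14c = 10)
  cal <- calibrate_14c(2800, 20, tc$terrestrial)
  s_tot <- sqrt(20^2 + 10^2)
  expect_lt(abs(cal$mean - 2800), 1)
  expect_equal(cal$sd, s_tot, tolerance = 0.01)
  # density matches the analytic Gaussian posterior pointwise
  grid <- cal$posterior$cal_bp
  analytic <- dnorm(grid, 2800, s_tot)
  analytic <- analytic / sum(analytic)
  expect_lt(max(abs(cal$posterior$density - analytic)), 1e-6)
  # HPD width ~ 2 * 1.96 sd for a Gaussian (discretisation slack of a few yr)
  width <- cal$hpd_range[["old"]] - cal$hpd_range[["young"]]
  expect_lt(abs(width - 2 * qnorm(0.977) * s_tot), 4)
})

test_that("posterior normalisation and HPD mass invariants hold", {
  tc <- toy_pair(slope = 1, wiggle_amp = 4, sigma_14c = 12)
  for (age in c(800, 2400, 5200)) {
    cal <- calibrate_14c(age, 30, tc$terrestrial)
    expect_equal(sum(cal$posterior$density), 1, tolerance = 1e-9)
    expect_true(all(cal$posterior$density >= 0))
    mass <- sum(cal$hpd$mass)
    expect_gte(mass, 0.949); expect_lte(mass, 0.959)
    expect_true(all(cal$hpd$old >= cal$hpd$young))
  }
  # narrower measurement error gives a narrower HPD envelope
  w <- function(s) {
    r <- calibrate_14c(2400, s, tc$terrestrial)$hpd_range
    r[["old"]] - r[["young"]]
  }
  expect_lt(w(10), w(40))
  expect_error(calibrate_14c(99000, 20, tc$terrestrial), "off curve")
})

test_that("round-trip coverage: true ages land inside the 95.4% HPD", {
  set.seed(140)
  tc <- toy_pair(slope = 1, wiggle_amp = 3, sigma_14c = 10)
  hits <- 0
  for (i in 1:100) {
    true_cal <- runif(1, 500, 5500)
    mu <- approx(tc$terrestrial$cal_bp, tc$terrestrial$mu, true_cal)$y
    meas <- rnorm(1, mu, sqrt(25^2 + 10^2))
    cal <- calibrate_14c(meas, 25, tc$terrestrial)
    inside <- any(cal$hpd$young <= true_cal & true_cal <= cal$hpd$old)
    hits <- hits + inside
  }
  expect_gte(hits, 92)
})

test_that("sensitivity grid reproduces single calls and known directions", {
  tc <- toy_pair(slope = 1, wiggle_amp = 0, reservoir_offset = 500,
                 sigma_14c = 15)
  # single cell == direct calibrate
  g1 <- sensitivity_grid(2980, 40, tc$terrestrial, tc$marine,
                         data.frame(mean = -140, sd = 35),
                         data.frame(mean = 0.5, sd = 0.1))
  direct <- calibrate_14c(
    2980, 40,
    mix_curves(tc$terrestrial, apply_reservoir(tc$marine, -140, 35), 0.5, 0.1)
  )
  expect_equal(g1$mean, direct$mean)
  expect_equal(g1$sd, direct$sd)
  expect_equal(nrow(g1), 1)

  # a marine curve sits 500 14C yr above the terrestrial one, so for a fixed
  # measurement a larger marine fraction attributes more of the measured age
  # to reservoir: the calibrated date gets younger, by the offset at p = 1
  gp <- sensitivity_grid(2980, 40, tc$terrestrial, tc$marine,
                         data.frame(mean = 0, sd = 0),
                         data.frame(mean = c(0, 1), sd = 0))
  expect_lt(gp$mean[gp$marine_fraction == 1],
            gp$mean[gp$marine_fraction == 0])
  expect_equal(gp$mean[gp$marine_fraction == 0] -
                 gp$mean[gp$marine_fraction == 1], 500, tolerance = 1)

  # more negative reservoir offsets give older calibrated dates
  gd <- sensitivity_grid(2980, 40, tc$terrestrial, tc$marine,
                         data.frame(mean = c(-250, -140, 168), sd = 0),
                         data.frame(mean = 0.5, sd = 0))
  expect_true(all(diff(gd$mean[order(gd$delta_r_mean)]) < 0))
  expect_error(sensitivity_grid(2980, 40, tc$terrestrial, tc$marine,
                                data.frame(mean = numeric(0), sd = numeric(0)),
                                0.5),
               "non-empty")
})
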