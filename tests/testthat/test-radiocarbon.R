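test_that("curve files read back correctly and malformed input is rejected", {
  f <- tempfile(fileext = ".14c")
  writeLines(c("# header", "0,150,10", "100,230,12"), f)
  cv <- load_curve(f)
  expect_s3_class(cv, "cal_curve")
  expect_length(cv$cal_bp, 2)
  expect_equal(curve_at(cv, 0)$c14_age, 150)

  # rows are sorted by increasing cal BP regardless of file order
  f2 <- tempfile(); writeLines(c("100,230,12", "0,150,10"), f2)
  expect_equal(load_curve(f2)$cal_bp, c(0, 100))

  f3 <- tempfile(); writeLines(c("0,150,10", "garbage line"), f3)
  expect_error(load_curve(f3), "line 2")
  f4 <- tempfile(); writeLines(c("0,150,0", "100,230,12"), f4)
  expect_error(load_curve(f4), "positive")
  f5 <- tempfile(); writeLines(c("0,150,10", "0,160,10"), f5)
  expect_error(load_curve(f5), "[Dd]uplicate")

  # csv dialect with header
  f6 <- tempfile(fileext = ".csv")
  writeLines(c("calbp,c14,err", "0,150,10", "100,230,12"), f6)
  expect_equal(load_curve(f6, dialect = "csv")$c14_age, c(150, 230))
})

test_that("curve interpolation is linear in both mean and sigma", {
  cv <- toy_curve()
  at50 <- curve_at(cv, 50)
  expect_equal(at50$c14_age, 190)
  expect_equal(at50$c14_sigma, 11)
  at25 <- curve_at(cv, 25)
  expect_equal(at25$c14_age, 170)
  expect_equal(at25$c14_sigma, 10.5)
  expect_equal(curve_at(cv, 100)$c14_age, 230)  # knot identity
  expect_error(curve_at(cv, 101), "span")
})

test_that("identity-curve calibration equals a discretized Gaussian", {
  cv <- identity_curve(sigma = 0)
  d <- calibrate(c14_date(1000, 20), cv)
  oracle <- stats::dnorm(d$grid, 1000, 20)
  oracle <- oracle / (sum(oracle) * d$delta)
  expect_lt(max(abs(d$density - oracle)) / max(oracle), 1e-8)
  expect_equal(sum(d$density) * d$delta, 1, tolerance = 1e-6)
  s <- summary(d)
  expect_equal(s$mu, 1000, tolerance = 0.5)
  expect_equal(s$sigma, 20, tolerance = 0.5)
  expect_equal(s$median, 1000, tolerance = 0.5)
})

test_that("a flat curve yields a uniform posterior", {
  cv <- cal_curve(c(500, 1500), c(1000, 1000), c(0, 0))
  d <- calibrate(c14_date(1000, 20), cv, grid_step = 10)
  expect_lt(diff(range(d$density)) / max(d$density), 1e-12)
  expect_equal(sum(d$density) * d$delta, 1, tolerance = 1e-6)
})

test_that("calibration fails cleanly when mass lies outside the curve span", {
  cv <- cal_curve(c(0, 500), c(0, 500), c(5, 5))
  expect_error(calibrate(c14_date(5000, 20), cv), "mass")
})

test_that("grid refinement changes the summary negligibly", {
  cv <- make_synthetic_curve("wiggly")
  for (age in c(400, 1100)) {
    d1 <- calibrate(c14_date(age, 30), cv, grid_step = 2)
    d2 <- calibrate(c14_date(age, 30), cv, grid_step = 1)
    s1 <- summary(d1); s2 <- summary(d2)
    expect_lt(abs(s1$mu - s2$mu), 0.5)
    expect_lt(abs(s1$median - s2$median), 0.5)
  }
})

test_that("HPD mass matches the requested level for unimodal and bimodal shapes", {
  cv <- identity_curve(sigma = 0)
  d <- calibrate(c14_date(1000, 20), cv)
  for (lev in c(0.68, 0.954)) {
    h <- summary(d, level = lev)$hpd
    expect_equal(sum(h$mass), lev, tolerance = 0.005)
    expect_true(all(h$lo < h$hi))
  }
  # symmetric bimodal: two disjoint HPD intervals, mean at the midpoint
  grid <- seq(500, 1500, by = 1)
  dens <- stats::dnorm(grid, 800, 30) + stats::dnorm(grid, 1200, 30)
  dens <- dens / sum(dens)
  bim <- structure(list(grid = grid, density = dens, delta = 1),
                   class = "cal_density")
  s <- summary(bim, level = 0.95)
  expect_equal(s$mu, 1000, tolerance = 1)
  expect_equal(nrow(s$hpd), 2)
  expect_equal(sum(s$hpd$mass), 0.95, tolerance = 0.005)

  # near-point-mass density: HPD collapses to a couple of grid cells
  spike <- stats::dnorm(grid, 1000, 0.6); spike <- spike / sum(spike)
  pm <- structure(list(grid = grid, density = spike, delta = 1),
                  class = "cal_density")
  h <- summary(pm, level = 0.9)$hpd
  expect_lte(sum(h$hi - h$lo), 3)
})

test_that("simulated determinations are centred on the curve value", {
  cv <- identity_curve(sigma = 0)
  # zero noise reproduces the curve exactly
  expect_equal(simulate_date(1000, cv, meas_error = 0)$c14_age, 1000)
  set.seed(42)
  m <- simulate_date(rep(1000, 2000), cv, meas_error = 20)$c14_age
  expect_lt(abs(mean(m) - 1000), 1.5)  # 3 * 20 / sqrt(2000)
  expect_equal(stats::sd(m), 20, tolerance = 0.1 * 20)
})

test_that("simulate-calibrate round trip is unbiased", {
  cv <- identity_curve(sigma = 10)
  set.seed(7)
  sims <- simulate_date(rep(1000, 500), cv, meas_error = 25)
  grid <- seq(700, 1300, by = 1)
  m <- burialfreq:::calibrate_matrix(sims$c14_age, sims$c14_error, cv, grid)
  p <- m  # rows are normalized densities
  cf <- t(apply(p, 1, cumsum))
  medians <- grid[apply(cf >= 0.5 / 1, 1, which.max)]
  expect_lt(abs(mean(medians) - 1000), 5)
})

test_that("cal BP and CE conversions are exact inverses", {
  expect_equal(calbp_to_ce(1950), 0)
  expect_equal(calbp_to_ce(0), 1950)
  expect_equal(calbp_to_ce(700), 1250)
  x <- c(-30, 0, 512.5, 2000)
  expect_equal(ce_to_calbp(calbp_to_ce(x)), x)
})
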