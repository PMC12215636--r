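cv <- identity_curve(sigma = 10)
grid250 <- model_grid(domain_ce = c(250, 1850))

direct_records <- function(ages_bp, err = 25, region = "NE") {
  sim <- simulate_date(ages_bp, cv, 0)  # exact curve values, no scatter
  data.frame(individual_id = sprintf("I%03d", seq_along(ages_bp)),
             site_id = "S1", region = region, tier = "direct",
             c14_age = sim$c14_age, c14_error = err,
             stringsAsFactors = FALSE)
}

test_that("an SPD of one record equals its calibrated density", {
  rec <- direct_records(1000)
  m <- spd(rec, cv, grid = grid250)
  d <- calibrate(c14_date(rec$c14_age, rec$c14_error), cv, grid = grid250)
  expect_equal(m$mean_density, d$density, tolerance = 1e-12)
})

test_that("SPDs are additive and normalizations behave", {
  rec <- direct_records(c(500, 1500))  # disjoint supports
  u <- spd(rec, cv, normalization = "unit", grid = grid250)
  delta <- u$grid[2] - u$grid[1]
  expect_equal(sum(u$mean_density) * delta, 1, tolerance = 1e-3)
  ce <- calbp_to_ce(u$grid)
  lobe1 <- sum(u$mean_density[u$grid < 1000]) * delta
  expect_equal(lobe1, 0.5, tolerance = 1e-3)

  cnt <- spd(rec, cv, normalization = "count", grid = grid250)
  expect_equal(sum(cnt$mean_density) * delta, 2, tolerance = 1e-3)

  # linearity under count normalization for disjoint record sets
  a <- spd(rec[1, ], cv, normalization = "count", grid = grid250)
  b <- spd(rec[2, ], cv, normalization = "count", grid = grid250)
  expect_equal(cnt$mean_density, a$mean_density + b$mean_density,
               tolerance = 1e-12)
})

test_that("an SPD over a known bimodal intensity recovers the modes", {
  set.seed(31)
  ages <- ce_to_calbp(c(stats::rnorm(50, 600, 60), stats::rnorm(50, 1500, 60)))
  rec <- direct_records(ages, err = 25)
  m <- spd(rec, cv, grid = grid250, seed = 32)
  ce <- calbp_to_ce(m$grid)
  early <- ce < 1000
  peak1 <- ce[early][which.max(m$mean_density[early])]
  peak2 <- ce[!early][which.max(m$mean_density[!early])]
  expect_lt(abs(peak1 - 600), 50)
  expect_lt(abs(peak2 - 1500), 50)
})

test_that("identical point ages give a single-kernel KDE with a null envelope", {
  rec <- direct_records(rep(1000, 8), err = 25)
  m <- kde_model(rec, cv, n_iter = 10, bandwidth = 30, grid = grid250,
                 seed = 1)
  # unimodal around 1000 BP, envelope tight around the mean
  expect_equal(m$grid[which.max(m$mean_density)], 1000, tolerance = 30)
  expect_true(all(m$lo_env <= m$mean_density + 1e-9))
  expect_true(all(m$hi_env >= m$mean_density - 1e-9))
  expect_lt(max(m$hi_env - m$lo_env), max(m$mean_density))
})

test_that("KDE mean integrates to one and the envelope brackets the mean", {
  cat0 <- generate_catalogue(hiatus_scenario(n_individuals = 60,
                                             master_seed = 9))
  chr <- estimate_site_chronologies(cat0$site_dates, cat0$curve, seed = 1)
  m <- kde_model(cat0$records, cat0$curve, chr, n_iter = 100, grid = grid250,
                 seed = 2, keep_iterations = TRUE)
  delta <- m$grid[2] - m$grid[1]
  expect_equal(sum(m$mean_density) * delta, 1, tolerance = 1e-3)
  expect_true(all(m$lo_env <= m$mean_density + 1e-9))
  expect_true(all(m$mean_density <= m$hi_env + 1e-9))
  # percentile envelope coverage over iteration-gridpoint pairs
  inside <- sweep(m$iterations, 2, m$lo_env, ">=") &
    sweep(m$iterations, 2, m$hi_env, "<=")
  expect_equal(mean(inside), 0.95, tolerance = 0.03)
})

test_that("an injected hiatus leaves a density trough", {
  hs <- generate_catalogue(hiatus_scenario())
  expect_equal(sum(hs$truth$true_age_ce >= 950 & hs$truth$true_age_ce <= 1200),
               0)
  chr <- estimate_site_chronologies(hs$site_dates, hs$curve, seed = 1)
  m <- kde_model(hs$records, hs$curve, chr, n_iter = 50, grid = grid250,
                 seed = 2)
  ce <- calbp_to_ce(m$grid)
  gap <- ce >= 950 & ce <= 1200
  flank <- min(max(m$mean_density[ce < 950]), max(m$mean_density[ce > 1200]))
  expect_lt(mean(m$mean_density[gap]) / flank, 0.25)
})

test_that("the injected NE/NW antiphase is recovered and persists across replicates", {
  ac <- generate_catalogue(antiphase_scenario())
  chr <- estimate_site_chronologies(ac$site_dates, ac$curve, seed = 11)
  ne <- filter_records(ac$records, region = "NE")
  nw <- filter_records(ac$records, region = "NW")
  mne <- kde_model(ne, ac$curve, chr, n_iter = 50, grid = grid250, seed = 3)
  mnw <- kde_model(nw, ac$curve, chr, n_iter = 50, grid = grid250, seed = 4)
  expect_lt(stats::cor(mne$mean_density, mnw$mean_density), -0.5)

  rne <- replicate_models(ne, ac$curve, chr, n_replicates = 10, n_iter = 30,
                          grid = grid250, seed = 21)
  rnw <- replicate_models(nw, ac$curve, chr, n_replicates = 10, n_iter = 30,
                          grid = grid250, seed = 22)
  rs <- mapply(function(a, b) stats::cor(a$mean_density, b$mean_density),
               rne, rnw)
  expect_true(all(rs < 0))
})

test_that("replicate sets are deterministic under a master seed", {
  rec <- direct_records(c(800, 900, 1000, 1100), err = 30)
  r1 <- replicate_models(rec, cv, n_replicates = 3, n_iter = 5,
                         grid = grid250, seed = 99)
  r2 <- replicate_models(rec, cv, n_replicates = 3, n_iter = 5,
                         grid = grid250, seed = 99)
  expect_identical(r1, r2)
  # a single replicate equals kde_model under the derived sub-seed
  s1 <- burialfreq:::derive_seeds(42, 1)
  one <- replicate_models(rec, cv, n_replicates = 1, n_iter = 5,
                          grid = grid250, seed = 42)
  direct <- kde_model(rec, cv, n_iter = 5, grid = grid250, seed = s1)
  expect_equal(one[[1]], direct)
})
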