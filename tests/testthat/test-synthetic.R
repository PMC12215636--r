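test_that("synthetic curves satisfy their structural guarantees", {
  idc <- make_synthetic_curve("identity", sigma = 7)
  expect_equal(curve_at(idc, 1000)$c14_age, 1000)
  expect_equal(curve_at(idc, 1000)$c14_sigma, 7)

  wg <- make_synthetic_curve("wiggly", amplitude = 20, period = 500)
  expect_lte(max(abs(wg$c14_age - wg$cal_bp)), 20)
  expect_true(all(diff(wg$c14_age) > 0))  # invertible: slope stays positive
  expect_error(make_synthetic_curve("wiggly", amplitude = 200, period = 500),
               "invertible")
})

test_that("catalogue generation is deterministic under the master seed", {
  cfg <- antiphase_scenario(master_seed = 123)
  a <- generate_catalogue(cfg)
  b <- generate_catalogue(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$site_dates, b$site_dates)
  expect_identical(a$truth, b$truth)
  p1 <- generate_proxy(seed = 5)
  p2 <- generate_proxy(seed = 5)
  expect_identical(p1, p2)
})

test_that("ground truth covers every record exactly once", {
  g <- generate_catalogue(default_scenario(master_seed = 4))
  expect_setequal(g$truth$individual_id, g$records$individual_id)
  expect_equal(anyDuplicated(g$truth$individual_id), 0)
  s <- summarize_catalogue(g$records)
  expect_equal(as.vector(s$n_by_region), c(181, 93, 40))
  expect_equal(s$n_sites, 60)
  # every non-direct record's site has associated dates to build a
  # chronology from
  indirect <- g$records$tier != "direct"
  expect_true(all(g$records$site_id[indirect] %in% g$site_dates$site_id))
})

test_that("tier frequencies follow the configured probabilities", {
  cfg <- scenario_config(list(
    NE = list(intensity = function(ce) rep(1, length(ce)),
              n_individuals = 10000, n_sites = 40)),
    tier_probabilities = c(0.25, 0.5, 0.25), curve_kind = "identity",
    master_seed = 6)
  g <- generate_catalogue(cfg)
  frac <- table(g$records$tier) / 10000
  expect_equal(as.vector(frac[c("direct", "medium", "poor")]),
               c(0.25, 0.5, 0.25), tolerance = 0.045)
})

test_that("a fully direct catalogue round-trips through CSV unchanged", {
  cfg <- scenario_config(list(
    NE = list(intensity = function(ce) rep(1, length(ce)),
              n_individuals = 25, n_sites = 5)),
    tier_probabilities = c(1, 0, 0), curve_kind = "identity", master_seed = 8)
  g <- generate_catalogue(cfg)
  expect_true(all(g$records$tier == "direct"))
  d <- tempfile("full_direct")
  paths <- write_catalogue(g, d)
  back <- read_catalogue(paths["burials"], paths["site_dates"])
  expect_equal(back$records$c14_age, g$records$c14_age)
  expect_equal(nrow(back$records), 25)
})

test_that("proxies are piecewise-constant at zero noise and null costs stay small", {
  p <- generate_proxy(c(1300, 1600), c(0, 1, 2), noise_sd = 0, seed = 1)
  expect_setequal(unique(p$x), c(0, 1, 2))
  expect_equal(p$x[p$t < 1300], rep(0, sum(p$t < 1300)))

  # cost improvement of k = 1 over k = 0 is marginal for a level signal
  # compared to a genuine step
  flat <- generate_proxy(changepoints_ce = numeric(0), levels = 1,
                         noise_sd = 0.3, seed = 2)
  stepped <- generate_proxy(changepoints_ce = 1050, levels = c(0, 1),
                            noise_sd = 0.3, seed = 2)
  rel_gain <- function(sig) {
    cost <- burialfreq:::segment_cost_fun(sig$x, "mean")
    k0 <- cost(1, length(sig$x))
    k1 <- detect_changepoints(sig, k = 1)$total_cost
    (k0 - k1) / k0
  }
  expect_lt(rel_gain(flat), 0.2)
  expect_gt(rel_gain(stepped), 0.5)
})

test_that("an identically zero intensity is a configuration error", {
  cfg <- scenario_config(list(
    NE = list(intensity = function(ce) rep(0, length(ce)),
              n_individuals = 5, n_sites = 2)), curve_kind = "identity")
  expect_error(generate_catalogue(cfg), "zero")
})
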