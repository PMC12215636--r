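# Shared fixtures: tiny synthetic curves and catalogues built in code.

identity_curve <- function(sigma = 0, span = c(-100, 2600)) {
  make_synthetic_curve("identity", span_bp = span, sigma = sigma)
}

# two-knot toy curve used for interpolation checks
toy_curve <- function() cal_curve(c(0, 100), c(150, 230), c(10, 12))

# a small all-direct catalogue with uniform true ages (homogeneous across
# regions); used for null-calibration checks of the permutation test
homogeneous_catalogue <- function(n = 60, regions = c("NE", "NW", "SE"),
                                  curve = identity_curve(sigma = 10),
                                  seed = 1) {
  set.seed(seed)
  ages <- ce_to_calbp(stats::runif(n, 300, 1800))
  sim <- simulate_date(ages, curve, 30)
  data.frame(individual_id = sprintf("I%03d", seq_len(n)),
             site_id = "SITE_X",
             region = rep_len(regions, n),
             tier = "direct",
             c14_age = sim$c14_age, c14_error = sim$c14_error,
             stringsAsFactors = FALSE)
}

# toy 3-row burial CSV pair on disk; returns the two paths
write_toy_catalogue <- function(dir = tempfile("cat")) {
  dir.create(dir, showWarnings = FALSE)
  burials <- data.frame(
    individual_id = c("A1", "B1", "B2"),
    site_id = c("S1", "S2", "S2"),
    region = c("NE", "NW", "NW"),
    tier = c("direct", "medium", "poor"),
    c14_age = c(900, NA, NA),
    c14_error = c(25, NA, NA))
  sites <- data.frame(site_id = c("S2", "S2"), lab_id = c("L1", "L2"),
                      c14_age = c(850, 870), c14_error = c(30, 30),
                      material = "charcoal")
  bp <- file.path(dir, "burials.csv"); sp <- file.path(dir, "site_dates.csv")
  utils::write.csv(burials, bp, row.names = FALSE)
  utils::write.csv(sites, sp, row.names = FALSE)
  c(burials = bp, site_dates = sp)
}
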