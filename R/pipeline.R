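#' Progressive confidence-tier models
#'
#' Fits three aggregate KDE models on a shared grid, progressively
#' incorporating the lower-confidence tiers: direct dates only, direct +
#' medium, and all three tiers. Comparing the three shows how the simulated
#' ages reshape the burial-frequency curve.
#'
#' @param records burial record data frame.
#' @param site_dates site-associated determinations.
#' @param curve a [cal_curve()].
#' @param n_iter bootstrap iterations per model.
#' @param grid calendar grid (default [model_grid()]).
#' @param meas_error laboratory error for simulated determinations, 14C yr.
#' @param seed master seed; each model gets a derived sub-seed.
#' @param chronologies optional precomputed site chronologies (estimated
#'   from `site_dates` when omitted).
#' @return Named list of three `density_model`s (`direct`, `medium`,
#'   `poor`), with the record count of each attached.
#' @export
run_tiered_models <- function(records, site_dates, curve, n_iter = 100,
                              grid = model_grid(), meas_error = 30,
                              seed = NULL, chronologies = NULL) {
  seeds <- derive_seeds(seed, 4)
  chronologies <- chronologies %||%
    estimate_site_chronologies(site_dates, curve, seed = seeds[4])
  out <- lapply(seq_along(TIERS), function(i) {
    sub <- filter_records(records, tier_max = TIERS[i])
    kde_model(sub, curve, chronologies, n_iter = n_iter, grid = grid,
              meas_error = meas_error, seed = seeds[i])
  })
  names(out) <- TIERS
  out
}

#' Site-exclusion leverage experiment
#'
#' Fits the full aggregate model and a companion model from which the
#' simulated (non-direct) records of the named sites are removed, on one
#' grid with one seed, quantifying the leverage of a few large assemblages
#' on the national curve.
#'
#' @inheritParams run_tiered_models
#' @param exclude_sites site ids whose simulated records are excluded from
#'   the second model.
#' @return List with `full` and `excluded` `density_model`s and
#'   `n_excluded`, the number of records removed.
#' @export
run_exclusion_model <- function(records, site_dates, curve, exclude_sites,
                                n_iter = 100, grid = model_grid(),
                                meas_error = 30, seed = NULL,
                                chronologies = NULL) {
  seeds <- derive_seeds(seed, 2)
  chronologies <- chronologies %||%
    estimate_site_chronologies(site_dates, curve, seed = seeds[2])
  reduced <- filter_records(records, exclude_sites = exclude_sites)
  list(full = kde_model(records, curve, chronologies, n_iter = n_iter,
                        grid = grid, meas_error = meas_error,
                        seed = seeds[1]),
       excluded = kde_model(reduced, curve, chronologies, n_iter = n_iter,
                            grid = grid, meas_error = meas_error,
                            seed = seeds[1]),
       n_excluded = nrow(records) - nrow(reduced))
}

#' Regional model suite
#'
#' Per-region aggregate KDE models, the mark-permutation test of regional
#' differences, and overlaid replicate models per region (the stability
#' check for features such as the NE/NW antiphase). With a single region the
#' permutation stage is skipped with a warning.
#'
#' @inheritParams run_tiered_models
#' @param n_replicates replicate models per region.
#' @param n_perm label permutations for the regional test.
#' @param verbose emit one progress line per stage.
#' @return List with `models` (per-region `density_model`s), `perm`
#'   (`perm_test` or `NULL`), `replicates` (per-region lists of replicate
#'   models).
#' @export
run_regional_suite <- function(records, site_dates, curve, n_iter = 100,
                               n_replicates = 10, n_perm = 999,
                               grid = model_grid(), meas_error = 30,
                               seed = NULL, chronologies = NULL,
                               verbose = FALSE) {
  seeds <- derive_seeds(seed, 4)
  note <- function(stage, n, t0) {
    if (verbose)
      message(sprintf("[%s] n=%d, %.1fs", stage, n,
                      as.numeric(Sys.time()) - t0))
  }
  t0 <- as.numeric(Sys.time())
  chronologies <- chronologies %||%
    estimate_site_chronologies(site_dates, curve, seed = seeds[4])
  note("chronologies", length(chronologies), t0)
  regions <- sort(unique(records$region))

  t0 <- as.numeric(Sys.time())
  rseeds <- derive_seeds(seeds[1], length(regions))
  models <- lapply(seq_along(regions), function(i)
    kde_model(filter_records(records, region = regions[i]), curve,
              chronologies, n_iter = n_iter, grid = grid,
              meas_error = meas_error, seed = rseeds[i]))
  names(models) <- regions
  note("regional models", length(regions), t0)

  perm <- NULL
  if (length(regions) >= 2) {
    t0 <- as.numeric(Sys.time())
    perm <- perm_test(records, curve, chronologies, n_perm = n_perm,
                      meas_error = meas_error, seed = seeds[2])
    note("permutation test", n_perm, t0)
  } else {
    warning("single region: permutation stage skipped", call. = FALSE)
  }

  t0 <- as.numeric(Sys.time())
  pseeds <- derive_seeds(seeds[3], length(regions))
  replicates <- lapply(seq_along(regions), function(i)
    replicate_models(filter_records(records, region = regions[i]), curve,
                     chronologies, n_replicates = n_replicates,
                     n_iter = n_iter, grid = grid, meas_error = meas_error,
                     seed = pseeds[i]))
  names(replicates) <- regions
  note("replicates", n_replicates, t0)

  list(models = models, perm = perm, replicates = replicates)
}
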