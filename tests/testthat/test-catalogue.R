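test_that("a toy catalogue reads back with validation intact", {
  paths <- write_toy_catalogue()
  ct <- read_catalogue(paths["burials"], paths["site_dates"])
  expect_equal(nrow(ct$records), 3)
  expect_equal(length(unique(ct$records$site_id)), 2)
  expect_equal(attr(ct, "n_dropped"), 0)

  # region outside the vocabulary is a validation error naming the row
  bad <- utils::read.csv(paths["burials"])
  bad$region[2] <- "XX"
  f <- tempfile(fileext = ".csv"); utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_catalogue(f, paths["site_dates"]), "B1")

  # direct tier without a determination is a row-level error
  bad2 <- utils::read.csv(paths["burials"])
  bad2$tier[2] <- "direct"
  f2 <- tempfile(fileext = ".csv"); utils::write.csv(bad2, f2, row.names = FALSE)
  expect_error(read_catalogue(f2, paths["site_dates"]), "B1")

  # missing mandatory column is a schema error
  bad3 <- utils::read.csv(paths["burials"]); bad3$region <- NULL
  f3 <- tempfile(fileext = ".csv"); utils::write.csv(bad3, f3, row.names = FALSE)
  expect_error(read_catalogue(f3, paths["site_dates"]), "region")
})

test_that("summaries conserve counts across partitions", {
  cat0 <- standin_catalogue(seed = 3)
  s <- summarize_catalogue(cat0$records)
  expect_equal(sum(s$n_by_region), s$n_individuals)
  expect_equal(sum(s$n_by_tier), s$n_individuals)
  expect_equal(sum(s$n_by_region_tier), s$n_individuals)
  expect_true(all(s$pct_simulated_by_region >= 0 &
                    s$pct_simulated_by_region <= 100))
})

test_that("filters are idempotent and region filters partition the catalogue", {
  cat0 <- standin_catalogue(seed = 2)
  f1 <- filter_records(cat0$records, region = "NW", tier_max = "medium")
  f2 <- filter_records(f1, region = "NW", tier_max = "medium")
  expect_identical(f1, f2)

  parts <- lapply(c("NE", "NW", "SE"), function(r)
    filter_records(cat0$records, region = r)$individual_id)
  expect_equal(sort(unlist(parts)), sort(cat0$records$individual_id))
  expect_equal(sum(lengths(parts)), nrow(cat0$records))

  # tier_max nests: direct within +medium within all
  d <- filter_records(cat0$records, tier_max = "direct")$individual_id
  m <- filter_records(cat0$records, tier_max = "medium")$individual_id
  expect_true(all(d %in% m))

  expect_equal(nrow(filter_records(cat0$records[0, ], region = "NE")), 0)
})

test_that("site exclusion removes only the simulated records of named sites", {
  cat0 <- standin_catalogue(seed = 1)
  # add a direct burial at an excluded site: it must survive the exclusion
  extra <- cat0$records[cat0$records$tier == "direct", ][1, ]
  extra$individual_id <- "KEEP_ME"; extra$site_id <- "K2"
  recs <- rbind(cat0$records, extra)
  kept <- filter_records(recs, exclude_sites = c("Schroda", "K2", "Mapungubwe"))
  expect_true("KEEP_ME" %in% kept$individual_id)
  expect_false(any(kept$tier != "direct" &
                     kept$site_id %in% c("Schroda", "K2", "Mapungubwe")))
  expect_warning(filter_records(recs, exclude_sites = "NoSuchSite"),
                 "NoSuchSite")
})

test_that("the full-scale stand-in reproduces the published margins", {
  cat0 <- standin_catalogue(seed = 1)
  s <- summarize_catalogue(cat0$records)
  expect_equal(s$n_individuals, 314)
  expect_equal(s$n_sites, 60)
  expect_equal(as.vector(s$n_by_tier), c(79, 166, 69))
  expect_equal(as.vector(s$n_by_tier_published), c(79, 156, 74))
  expect_equal(s$n_unclassified_published, 5)
  expect_equal(as.vector(s$n_by_region), c(181, 93, 40))
  expect_equal(round(as.vector(s$pct_simulated_by_region)), c(90, 53, 60))

  excl <- filter_records(cat0$records, exclude_sites = cat0$exclusion_sites)
  expect_equal(nrow(cat0$records) - nrow(excl), 153)

  n_direct <- nrow(filter_records(cat0$records, tier_max = "direct"))
  n_medium <- nrow(filter_records(cat0$records, tier_max = "medium"))
  expect_equal(n_direct, 79)
  expect_equal(n_medium - n_direct, 166)

  # round trip through CSV preserves everything relevant
  d <- tempfile("stand_in")
  paths <- write_catalogue(cat0, d)
  back <- read_catalogue(paths["burials"], paths["site_dates"])
  expect_equal(nrow(back$records), 314)
  expect_equal(summarize_catalogue(back$records)$n_by_tier, s$n_by_tier)
})
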