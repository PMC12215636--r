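#!/usr/bin/env Rscript

# Build the synthetic stand-in burial catalogue (published margins: 314
# individuals, 60 sites, three regions, three confidence tiers) and report
# its accounting, including both confidence tallies and the per-region
# share of simulated ages.

library(burialfreq)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cat0 <- standin_catalogue(seed = 1)
paths <- write_catalogue(cat0, file.path(out_dir, "catalogue"))
message("catalogue written to ", dirname(paths[1]))

ct <- read_catalogue(paths["burials"], paths["site_dates"])
s <- summarize_catalogue(ct$records)
print(s)

tallies <- data.frame(
  quantity = c("individuals", "sites",
               "tier direct", "tier medium (model)", "tier poor (model)",
               "tier medium (published)", "tier poor (published)",
               "published unclassified",
               "region NE", "region NW", "region SE",
               "pct simulated NE", "pct simulated NW", "pct simulated SE"),
  value = c(s$n_individuals, s$n_sites,
            s$n_by_tier[["direct"]], s$n_by_tier[["medium"]],
            s$n_by_tier[["poor"]],
            s$n_by_tier_published[["medium"]],
            s$n_by_tier_published[["poor"]],
            s$n_unclassified_published,
            s$n_by_region[["NE"]], s$n_by_region[["NW"]],
            s$n_by_region[["SE"]],
            round(s$pct_simulated_by_region[["NE"]], 1),
            round(s$pct_simulated_by_region[["NW"]], 1),
            round(s$pct_simulated_by_region[["SE"]], 1)))
utils::write.csv(tallies, file.path(out_dir, "catalogue_tallies.csv"),
                 row.names = FALSE)
message("tallies written; note the two tier tallies are reported side by ",
        "side, never reconciled")
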