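#!/usr/bin/env Rscript

# Leverage of the three large Shashe-Limpopo assemblages: refit the full
# aggregate model with the 153 simulated ages from Schroda, K2 and
# Mapungubwe removed and compare the two curves.

library(burialfreq)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cat0 <- standin_catalogue(seed = 1)
ex <- run_exclusion_model(cat0$records, cat0$site_dates, cat0$curve,
                          exclude_sites = cat0$exclusion_sites,
                          n_iter = 100, seed = 21)
cfg_tag <- paste("config",
                 burialfreq:::config_hash(list(seed = 21,
                                               excl = cat0$exclusion_sites)))
export_density_model(ex$full, file.path(out_dir, "exclusion_full.csv"),
                     comment = cfg_tag)
export_density_model(ex$excluded, file.path(out_dir, "exclusion_reduced.csv"),
                     comment = cfg_tag)

ce <- calbp_to_ce(ex$full$grid)
mia <- ce >= 1000 & ce <= 1300
message(sprintf("%d simulated ages excluded (%s)", ex$n_excluded,
                paste(cat0$exclusion_sites, collapse = ", ")))
message(sprintf(
  "density over 1000-1300 CE: full %.3g vs reduced %.3g (count scale: %.1f vs %.1f records)",
  mean(ex$full$mean_density[mia]), mean(ex$excluded$mean_density[mia]),
  mean(ex$full$mean_density[mia]) * ex$full$n_records,
  mean(ex$excluded$mean_density[mia]) * ex$excluded$n_records))
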