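#!/usr/bin/env Rscript

# Change-point analysis of the regional burial-density curves and of
# synthetic proxy series with known transitions. Real palaeoenvironmental
# records can be substituted via read_signal() on a two-column CSV
# (age_CE, value); here synthetic proxies with transitions at 1300 and
# 1600 CE stand in for them.

library(burialfreq)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

# segment the regional burial curves fitted by 04_regional_models.R
for (rn in c("NE", "NW", "SE")) {
  f <- file.path(out_dir, sprintf("regional_model_%s.csv", rn))
  if (!file.exists(f)) {
    message("run 04_regional_models.R first; skipping ", rn)
    next
  }
  df <- utils::read.csv(f, comment.char = "#")
  sig <- signal(df$cal_CE, df$mean_density)
  r <- detect_changepoints(sig, k = 2, statistic = "mean")
  export_changepoints(r, file.path(out_dir,
                                   sprintf("changepoints_burials_%s.csv", rn)))
  message(sprintf("burial curve %s: mean shifts at %s CE", rn,
                  paste(round(r$times), collapse = " and ")))
}

# synthetic stand-in proxies with injected transitions
set.seed(51)
proxy <- generate_proxy(c(1300, 1600), c(0, -1, -2.2), noise_sd = 0.3,
                        sampling = "jittered")
uniform <- resample_to_uniform(proxy, 10)
for (stat in c("mean", "rms")) {
  r <- detect_changepoints(uniform, k = 2, statistic = stat)
  export_changepoints(r, file.path(out_dir,
                                   sprintf("changepoints_proxy_%s.csv", stat)))
  message(sprintf("synthetic proxy (%s statistic): detected %s CE (true 1300, 1600)",
                  stat, paste(round(r$times), collapse = ", ")))
}
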