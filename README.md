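# burialfreq

Reconstructing event-frequency curves from radiocarbon evidence is routine
when every record carries its own determination. Burial catalogues rarely
look like that: for southern African agriculturalist ("Iron Age") contexts,
most excavated individuals were never directly dated — their age rests on
the radiocarbon chronology of the settlement they were buried in. Ignoring
them biases any dates-as-data demographic proxy; the best-documented
example is the near-invisibility of the large Shashe-Limpopo assemblages
(Schroda, K2, Mapungubwe) in curves built from direct dates alone.

`burialfreq` implements a pipeline for exactly this situation, aimed at
archaeologists and palaeodemographers working with mixed-confidence
catalogues:

1. **Calibration** — single determinations are calibrated against a
   tabulated curve (IntCal/SHCal20 text format) under a flat calendar
   prior: `p(t | m) ∝ exp(−(m − c(t))² / 2(σ_m² + σ_c(t)²)) / √(σ_m² + σ_c(t)²)`,
   summarised as µ ± σ, median, and HPD intervals.
2. **Site chronologies** — each site's associated (charcoal) dates are
   calibrated, sampled, and pooled into a Gaussian KDE whose moments give
   the occupation estimate µ ± σ.
3. **Age simulation** — indirectly dated burials receive simulated
   determinations `m ~ N(c(t*), √(σ_c² + σ_lab²))` at calendar ages `t*`
   drawn from their site chronology, the standard simulated-determination
   device for incorporating undated records.
4. **Aggregate models** — summed probability distributions (SPD) and a
   bootstrap aggregate KDE with a pointwise percentile envelope; simulated
   ages are refreshed between iterations so their uncertainty propagates
   into the envelope.
5. **Regional comparison** — a mark-permutation test (region labels
   permuted over records) with per-region envelopes, deviation intervals,
   and exact global p-values.
6. **Change points** — exact dynamic-programming segmentation of burial
   or proxy time series where the segment mean (or RMS level) shifts most.
7. **Synthetic data** — scenario generators with known ground truth
   (per-site clustering, three confidence tiers, three regions, injected
   hiatus / antiphase structure) so every stage is testable end to end,
   plus a deterministic stand-in catalogue matching the published margins
   of the South African agriculturalist burial record.

## Worked example

```r
library(burialfreq)

cat0 <- standin_catalogue(seed = 1)   # synthetic stand-in catalogue
summarize_catalogue(cat0$records)
#> Burial catalogue: 314 individuals, 60 sites
#>   by tier (analysis):   direct=79, medium=166, poor=69
#>   by tier (published):  direct=79, medium=156, poor=74  (+5 unclassified)
#>   by region:  NE=181, NW=93, SE=40
#>   % simulated ages:  NE=89.5%, NW=52.7%, SE=60.0%

tiers <- run_tiered_models(cat0$records, cat0$site_dates, cat0$curve,
                           n_iter = 100, seed = 11)
```

The three tiered models report modal burial frequencies at 545 CE (direct
dates only, 79 records) and 1090 CE (once the 166 medium-confidence
simulated ages join, 245 records): the direct-date curve misses the
medieval peak entirely, because the assemblages that dominate it were
dated through their settlements. Excluding those three sites again,

```r
ex <- run_exclusion_model(cat0$records, cat0$site_dates, cat0$curve,
                          exclude_sites = cat0$exclusion_sites,
                          n_iter = 100, seed = 21)
ex$n_excluded
#> [1] 153
```

drops the mean 1000–1300 CE density from 0.00126 to 0.00041 per year — a
three-fold fall showing how much of the national curve those assemblages
carry. The regional permutation test (see `analysis/04_regional_models.R`)
finds all three regions deviating from the pooled distribution
(p = 0.001 at 999 permutations), and the NE/NW replicate correlations are
negative in 10 of 10 replicate models.

The `analysis/` directory holds the full sequence as numbered drivers
(catalogue accounting, tiered models, exclusion experiment, regional
suite, change points), each writing CSV tables under `results/`.

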