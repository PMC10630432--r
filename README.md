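# SASVtrace

Tools for tracing oceanic particle export with **shared amplicon sequence
variants (SASVs)**: prokaryote 16S rRNA ASVs found both in suspended
water-column communities and in sinking particles collected by sediment
traps. Because sinking particles entrain suspended microbes on their way
down, the depth profile of the summed relative abundance of trap-shared
ASVs records where exported particles pick up their microbial cargo. The
package is written for microbial oceanographers and biogeochemists who
have marker-gene count tables from paired water-column and sediment-trap
sampling (or who want to validate such an analysis on synthetic data
first).

## What it computes

* **SASV identification** — exact-sequence matching (optional N-wildcard)
  of trap ASVs against a monthly water-column climatology (unweighted
  means across years, replicates averaged first, calendar-adjacent-month
  interpolation of gaps), or directly against contemporaneous water
  samples.
* **Depth profiles** — per (trap interval, depth): the water-column SASV
  fraction and the trap SASV fraction by origin depth, summarized over
  time as mean / sd / n per depth.
* **Power-law attenuation fits** — the Martin-curve form

  `S_Z = S_ref * (Z / Z_ref)^b`

  fitted by nonlinear least squares on the linear scale (log–log
  regression as initialization), with linear-scale R², a two-sided
  p-value for b = 0 (t statistic, df = n − 2) and a two-sigma 95%
  confidence interval. Upper-ocean attenuation is anchored at
  Z_ref = 75 m; the deep increase below the ~250 m transition is fitted
  with Z_ref = 250 m. Per-interval fits give a *b* time series, which can
  be correlated with environmental covariates (Spearman by default).
* **Depth-zone classification** — SASVs reaching ≥ 0.1% of the water
  column at some depth are assigned to six zones (Surface 5–75 m, DCM
  100–150 m, Lower Euphotic 175–200 m, Upper Mesopelagic 225–500 m,
  Lower Mesopelagic 770–1000 m, Bathypelagic 2000–4000 m) from their
  profile maxima, with explicit retention rules for bimodal profiles.
* **Summer export pulse (SEP) enrichment** — intervals whose particulate
  C *and* N fluxes reach 150% of the annual reference means are flagged
  SEP; Welch's t-test with a direction gate identifies SASVs enriched in
  the deep trap during SEP.
* **A synthetic community generator** that plants the attenuation
  exponents, depth-zone ecotypes and SEP pulses, so the whole chain is
  verifiable by parameter recovery (see `vignettes/sasv-export-tracing.Rmd`
  for the model and its design margins).

## Worked example

Simulate the default study conditions (19 depths spanning 5–4000 m, two
years of monthly water sampling, 58 twelve-day trap intervals, 1e5 reads
per sample, planted S_75 = 0.829, b_upper = −1.34, transition at 250 m,
b_deep = +0.31) and run the full pipeline:

```r
library(SASVtrace)
cfg <- pipelineConfig(sim = simConfig(), seed = 1)
res <- runPipeline(cfg, outdir = "sasv_run")
res$upperFit
#> PowerLawFit: S_Z = S_75 * (Z/75)^b
#>   S_75 = 82.92%, b = -1.341 (2-sigma CI -1.342..-1.34)
#>   R2 = 1, p = 2.19e-16, n = 7, window 75-225 m
res$deepFit
#> PowerLawFit: S_Z = S_250 * (Z/250)^b
#>   S_250 = 16.5%, b = 0.3104 (2-sigma CI 0.3098..0.3109)
#>   R2 = 1, p = 1.44e-19, n = 9, window 250-4000 m
head(res$waterProfile, 4)
#>   depth_m      mean           sd  n
#> 1       5 0.8287552 0.0008356471 58
#> 2      25 0.8291092 0.0007239619 58
#> 3      45 0.8289804 0.0009364792 58
#> 4      75 0.8291204 0.0007839370 58
subset(res$enrichment, enriched)[, c("asv_id", "mean_sep", "mean_nonsep")]
#>                     asv_id   mean_sep mean_nonsep
#> 39     eco_copio_colwellia 0.09486091  0.02445362
#> 40     eco_copio_moritella 0.09420000  0.02446681
#> 41 eco_copio_halarcobacter 0.09451818  0.02442766
```

Reading: the time-averaged water-column SASV fraction sits near 83% in
the mixed layer, attenuates as (Z/75)^−1.34 down to 225 m (both planted
parameters recovered from noisy counts, R² = 1 to display precision, the
decay highly significant), then rises as (Z/250)^+0.31 below the
transition. The three planted copiotroph ecotypes — and nothing else —
come out enriched in the trap during the summer export pulse, with SEP
means about four-fold above non-SEP means. `sasv_run/` holds the fraction
table, profiles, fit JSONs, the b time series, zone assignments,
composition, SEP calendar, enrichment table and a `manifest.json`;
rerunning the same config and seed reproduces every file bit-identically.

Real datasets enter through `readAsvDataset(counts, fasta, metadata)`
(ASV × sample TSV/CSV, FASTA with optional taxon labels as descriptions,
sample metadata CSV) and `readFluxTable()`; `inst/scripts/sasv-pipeline.R`
wraps the same pipeline for shell use with a YAML config.

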