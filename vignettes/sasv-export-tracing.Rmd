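---
title: "Tracing sinking-particle export with shared ASVs: models and methods"
author: "SASVtrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing sinking-particle export with shared ASVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(SASVtrace))
```

## The tracer idea

A large share of the organic carbon fixed by oceanic photosynthesis leaves
the surface ocean on gravitationally sinking particles. Those particles
entrain suspended microbes on their way down, so a prokaryote 16S rRNA
amplicon sequence variant (ASV) that occurs **both** in suspended
water-column communities **and** in sinking particles collected by a
sediment trap — a *shared ASV*, or SASV — carries information about where
in the water column exported particles acquired their microbial cargo.

Two summary statistics drive everything in this package:

* the **water-column SASV fraction** at depth $Z$: the summed relative
  abundance, in the suspended community at $Z$, of the ASVs shared with a
  given trap; and
* the **trap SASV fraction by origin depth**: the summed relative
  abundance, in the trap sample itself, of the ASVs shared with the water
  column at $Z$. An ASV found at several depths contributes its full trap
  abundance at each, so these fractions may sum past one across depths.

In the epipelagic zone the water-column fraction attenuates with depth the
way particle flux does, and is modelled with the same power law used for
the Martin curve,

$$S_Z = S_{Z_\mathrm{ref}} \left( \frac{Z}{Z_\mathrm{ref}} \right)^{b},$$

with $Z_\mathrm{ref} = 75$ m by default (the base of the mixed layer at
the study site, below which net community production is small). Below a
transition near 250 m the trend reverses: deep communities contribute
*more* to the traps with increasing depth, and the same functional form
with a positive exponent and $Z_\mathrm{ref} = 250$ m describes the rise.

## Data model

The central container is `AsvExperiment`, a `SummarizedExperiment` whose
assay is the ASV-by-sample matrix (`"counts"` or `"relative"` mode),
whose `rowData` carries each ASV's DNA sequence (A/C/G/T/N; sequences are
uppercased and U is mapped to T on load) and optional taxon label, and
whose `colData` carries compartment (`water`/`trap`), depth, collection
dates and the derived calendar month. A trap collection interval is
assigned the month of its midpoint; a water sample, the month of its
date. All statistics operate on relative abundances
(`relativeAbundance()`), with all-zero samples preserved and flagged
rather than dropped.

## Monthly climatology and SASV identification

Water-column sampling is roughly monthly but trap intervals are roughly
twelve days, so trap samples are compared against a **monthly
climatology**: for each (depth, calendar month), the unweighted mean
across years of the per-sample relative-abundance vectors. Averaging is
staged — replicates within one (depth, date) first, then dates within a
(depth, year, month), then years — so uneven sampling cannot weight one
year over another. Every stage is a convex combination, so climatology
vectors stay normalized. A missing (depth, month) is filled with the
elementwise mean of the two calendar-adjacent months (December and
January are adjacent); only originally observed months serve as sources,
an unfillable gap is a hard error naming the entry, and a
nearest-observed-month fallback is available behind `allowNearest`.

A SASV is then an ASV with nonzero abundance in a trap sample whose
sequence is **exactly identical** to a water ASV with nonzero climatology
abundance at the (depth, month) under comparison. Exact string equality
is the right default because upstream ASV processing conventions (such as
masking one low-quality base position as N in every sequence) apply to
both compartments of one study identically. For mixed-provenance
datasets, `nWildcard = TRUE` additionally matches equal-length sequences
that differ only where either carries an N. Presence means relative
abundance strictly greater than zero; a floor is configurable via
`minPresence`. The water-fraction denominator is the full normalized
water vector at that (depth, month), not just the matched subset.

## Power-law fitting

`fitPowerLaw()` fits $S_Z = S_\mathrm{ref}(Z/Z_\mathrm{ref})^b$ by
unweighted nonlinear least squares **on the linear scale** with both
parameters free, using Levenberg–Marquardt (`minpack.lm::nlsLM`) started
from an ordinary log–log regression. Fitting on the linear scale (rather
than settling for log–log OLS) weights the shallow, large-abundance
depths the way standard curve-fitting routines with default settings do;
the log–log solution serves only as the initial value. Time-averaged
curves are fitted to the per-depth *means* across intervals, not the
per-interval points.

Reported statistics:

* $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ on the linear scale,
  undefined for a zero-variance profile;
* a two-sided p-value for $b = 0$ from the t statistic of $b$ with its
  standard error taken from the NLS covariance and $n - 2$ degrees of
  freedom. (This is a deliberate standardization: legacy analyses of this
  kind cite a curve-fitting website whose exact p-value recipe is not
  recoverable; the t-based value is flagged in the serialized output
  metadata.);
* a 95% confidence interval for $b$ as $b \pm 2\,\mathrm{SE}(b)$
  (two-sigma convention).

Numerical edge cases are explicit: a constant profile returns $b = 0$,
undefined $R^2$ and $p = 1$ without invoking the optimizer; a two-point
fit is the exact closed-form solution with no error estimate; a
zero-residual fit with nonzero slope reports the smallest representable
p-value rather than zero, keeping $p \in (0, 1]$. Depth windows are
inclusive; the default upper window is 75–225 m (shallower depths violate
the power-law regime, and the attenuation law is not extrapolated across
the deep transition), and the deep fits use 250 m and below.
`refitReference()` re-anchors a fit at another reference depth — on exact
power-law data $b$ is reference-invariant and
$S_\mathrm{new} = S_\mathrm{old}(Z_\mathrm{new}/Z_\mathrm{old})^b$, which
doubles as a self-check. `fitPerInterval()` produces the per-interval $b$
time series, skipping (with a warning) intervals with fewer than two
usable depths, and `correlateBCovariates()` relates the series to
environmental covariates by Spearman rank correlation on
pairwise-complete pairs (Pearson optional), reporting constant covariates
as undefined rather than failing.

## Depth-zone classification

SASVs whose time-averaged water-column profile reaches at least 0.1%
(inclusive) at some depth are classified by their profile maxima into six
depth zones: Surface (5–75 m), DCM (100–150 m), Lower Euphotic
(175–200 m), Upper Mesopelagic (225–500 m), Lower Mesopelagic
(770–1000 m) and Bathypelagic (2000–4000 m). A peak is a value strictly
greater than both neighbours; a plateau counts once at its shallowest
depth. Boundary depths count as peaks by default (`edgePeaks = TRUE`):
this deviates from the boundary-excluding default of common peak-finder
routines, deliberately, because surface-peaked taxa — maximal at the
shallowest sampled depth — must be classifiable at all; the flag restores
the excluding behaviour for comparison. Depths between zone bounds (only
possible on custom grids) go to the zone with the nearest bound-interval
midpoint.

Single-peak SASVs take their peak's zone. Bimodal SASVs are retained when
exactly one peak exceeds the depth-averaged mean of the profile (rule 1,
taking that peak's zone — the mean uses **all** grid depths, zeros
included) or when both peaks share a zone (rule 2); all other bimodal and
all >2-peak profiles are excluded with a reason. The bookkeeping
identity `single + bimodal + multimodal + no_peak = abundant` and
`retained + excluded = abundant` holds exactly, and classification is
invariant to any common positive rescaling of the profiles.

## Summer export pulse and enrichment

The summer export pulse (SEP) is flagged from flux data: an interval is
SEP when **both** its particulate carbon and particulate nitrogen fluxes
reach 150% of their annual reference means (inclusive; the conjunction is
the documented rule, and an `any` flag relaxes it). Enrichment compares
each trap-present ASV's relative abundances in SEP versus non-SEP
intervals with Welch's unequal-variance t-test, requiring at least two
intervals per stratum. An ASV is *enriched* when the two-sided p-value is
below $\alpha = 0.05$ **and** its SEP mean exceeds its non-SEP mean: the
direction gate makes the effective one-sided null rate $\alpha/2$, which
the calibration tests check alongside the two-sided rate. Whether the
original convention was one-sided or two-sided-with-direction is
ambiguous; the two-sided-plus-gate reading is adopted and recorded in the
run manifest. No multiple-testing correction is applied by default,
matching the uncorrected $p < 0.05$ convention of this literature; a
Benjamini–Hochberg option exists and always yields a subset of the
uncorrected enriched set.

## The synthetic-data generator

`simulateDataset()` builds a paired water/trap world in which every
downstream answer is known:

* **Shared-fraction target.** At each grid depth $Z$ the expected water
  community is split into ecotype ("shared") ASVs, whose summed relative
  abundance equals the planted piecewise law — constant above 75 m,
  $S_{75}(Z/75)^{b_\mathrm{up}}$ from 75 m to the 250 m transition,
  $S_{250}(Z/250)^{b_\mathrm{deep}}$ below, continuous at the transition —
  and one depth-specific unshared filler ASV absorbing the remainder.
  Fillers never enter the trap, so in noiseless mode the recovered water
  fraction equals the target to machine precision, and an infeasible
  target ($S > 1$ anywhere) is rejected before any sampling.
* **Ecotypes.** Each ecotype's depth profile is a Gaussian bump in
  $\log_{10}$ depth with width 5% of its peak depth (one or two bumps for
  bimodal ecotypes). The narrow default is a designed margin: within the
  shared pool, profiles are rescaled depth-by-depth to meet the target
  fraction, and the rescaling ratio between adjacent grid depths is
  bounded well below the bump's own adjacent-depth decay (about 10-fold
  at the closest grid spacing), so a planted maximum cannot migrate to a
  neighbouring depth and planted zones are recovered exactly. The default
  panel places two ecotypes at every grid depth (with realistic taxon
  labels per zone) so the pool is populated everywhere.
* **Seasonality.** Three copiotroph ecotypes (Colwellia-, Moritella- and
  Halarcobacter-like) receive a 5-fold multiplier in trap samples whose
  interval midpoint falls in July or August, before renormalisation;
  other taxa are correspondingly diluted, which exercises the direction
  gate from both sides. Flux records are drawn so SEP intervals exceed
  1.5x both reference means and non-SEP intervals exceed neither.
* **Noise.** Counts are multinomial draws at `readsPerSample` reads
  (default 1e5) under a single seed — the summed shared count at a depth
  is then exactly binomial, giving a closed-form standard error used as
  the sampling-noise oracle in the tests — or exact expected fractions in
  `"noiseless"` mode. ASV sequences are unique random 250-mers.

Default study conditions (chosen once, as the conditions the package is
validated under): a 19-depth grid at the canonical bottle depths from 5 m
to 4000 m, two years of monthly water sampling, and 58 consecutive
12-day trap intervals starting 2014-03-27 with planted
$S_{75} = 0.829$, $b_\mathrm{up} = -1.34$, transition at 250 m and
$b_\mathrm{deep} = +0.31$.

What the generator does **not** emulate — and hence what passing recovery
tests do not establish about field data: month-to-month change in the
water column (the expected community is stationary, so the climatology
machinery is exercised but seasonal succession is not), compositional
correlation between taxa beyond the multinomial constraint, sequencing
error and chimeras, depth-dependent read depth, particle-sinking physics,
and any taxonomy assignment process (labels are inputs).

## Validation scale and determinism

The shipped tests run the full pipeline at the default problem size:
noiseless recovery of both exponents to $10^{-6}$ in a few seconds; a
20-seed stochastic study at $10^5$ reads per sample recovering the
planted upper exponent to within 0.05 with every per-seed fit significant;
a 120-ecotype classification panel (100 unimodal, 20 bimodal split
10/5/5 across the retention rules) recovered exactly; the NLS fitter
checked against a dense grid search over $b$ (step 0.001, conditionally
optimal $S_\mathrm{ref}$ in closed form) on dozens of small noisy
profiles; and 1000-replicate calibration of the Welch null. All
randomness flows from one seed; identical configurations reproduce
datasets and on-disk pipeline products bit-identically (manifests carry
no timestamps for this reason).

## Worked example

```{r example, eval = FALSE}
library(SASVtrace)
cfg <- pipelineConfig(sim = simConfig(readsPerSample = "noiseless"),
                      seed = 1)
res <- runPipeline(cfg, outdir = tempfile("sasv_run"))
res$upperFit     # attenuation above the transition
res$deepFit      # deep rise below it
res$zoneCounts   # classification bookkeeping
subset(res$enrichment, enriched)
```

## Known limitations

* Exact sequence matching presumes consistent upstream ASV processing
  between compartments; heterogeneous pipelines need the N-wildcard, and
  anything fuzzier (OTU-style grouping) is out of scope.
* The p-value convention for $b$ is the t-based standardization described
  above, not a reproduction of any specific legacy recipe.
* Enrichment is a per-taxon Welch test on relative abundances;
  compositional (log-ratio) differential-abundance methods are not
  implemented.
* The per-interval $b$ series treats intervals as independent; no
  autocorrelation structure is modelled.
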