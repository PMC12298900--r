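---
title: "Reconstructing fish-mercury meta-data and assessing dietary exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing fish-mercury meta-data and assessing dietary exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishmerc)
```

## The problem

Mercury reaches Amazonian food webs from naturally enriched soils, gold
mining and reservoir flooding; as methylmercury it biomagnifies, so
carnivorous fish carry more than non-carnivorous ones, and limnology matters:
acidic, DOC-rich black waters favour methylation and uptake. Published
measurements, however, come as *report-level summaries* — a study publishes
the mean, SD and sample size of muscle Hg (µg/g wet weight) for one genus at
one site — and the assembled databases are rarely deposited. This package
implements the full computational chain for working with such data: a
validated report-level database model, regeneration of individual-level
pseudo-observations from the summaries, a linear-model suite for the
ecological drivers of fish Hg, and a dietary exposure risk engine for the
human populations that eat the fish.

## Report model and pseudo-data reconstruction

A report carries `(hg_mean, hg_sd, n_samples)` plus covariates: genus (six
regional genera with a fixed genus-to-habit mapping: *Cichla*, *Hoplias*,
*Plagioscion* carnivores; *Leporinus*, *Semaprochilodus*, *Schizodon*
non-carnivores), ecosystem type (river, lake, hydroelectric, market), water
type (black, white, clear; unrecorded only for market fish), total length,
and provenance fields. `read_reports()`/`write_reports()` exchange a fixed
CSV schema and validate every row; validation is row-local, so the accepted
set never depends on row order.

`reconstruct()` draws, for each report, `n_samples` values from
`Normal(hg_mean, hg_sd)`. Two choices deserve comment:

* **Positivity.** A normal with mean 0.05 and SD 0.2 puts appreciable mass
  below zero, where a log transform is undefined. The default
  (`positivity = "redraw"`) therefore redraws non-positive values, i.e. uses
  the zero-truncated normal; `positivity = "raw"` keeps the literal normal
  draws for moment-fidelity checks (the truncated mean exceeds the
  untruncated one, which the tests verify against a rejection sampler).
* **Substreams.** Each report's draws come from an RNG substream keyed by
  `(seed, report_id)`. Reconstructing any subset of reports reproduces the
  corresponding rows of a full run exactly, which makes subset analyses and
  tests composable.

Reports without an SD cannot constrain a spread and are excluded (listed
with reasons), never imputed.

### Inference on pseudo-data: the clustering problem

Pseudo-observations within a report all derive from that report's *estimated*
mean, so they share its sampling error: rows are clustered by report, with an
intra-class correlation of roughly `1/(n_r + 1)`. An individual-level OLS fit
treats them as independent and understates standard errors by a factor
approaching `sqrt(2)` for moderate `n_r`, which would drive 95% intervals to
roughly 83% coverage. Regression inference in this package therefore defaults
to CR (HC1-type) cluster-robust variances on `report_id`
(`sandwich::vcovCL`); the classical option is retained for comparison with
naive individual-level analyses. Simulation (100 seeded replicates of the
default 455-report configuration) puts the cluster-robust coverage of all
eleven injected effects at 92–98%.

## The linear-model suite

* **Transform.** `boxcox_select()` profiles the Box-Cox log-likelihood on a
  fixed grid, λ ∈ [−2, 2] in steps of 0.01, and returns the raw argmax (λ = 0
  handled as the natural log). The published analyses use the plain log, so
  all suite functions accept `transform = "log"` (the default) alongside
  `"boxcox"`.
* **ANOVA.** `anova_oneway()` is the classical one-way decomposition on the
  transformed scale, run separately per feeding habit for ecosystem type and
  water type; market rows (water unrecorded) are dropped from the water-type
  analysis. α = 0.05 throughout; no cross-model multiplicity correction is
  applied, mirroring the original two-ANOVA design.
* **Tukey letters.** `tukey_letters()` takes Tukey–Kramer adjusted p-values
  (studentized range with unequal-n standard errors, via `TukeyHSD`) and
  builds a compact letter display with the insert-and-absorb algorithm, so
  that two levels share a letter **iff** their adjusted p ≥ α. The tests
  check this biconditional programmatically on every run, and check the k = 2
  identity (adjusted p equals the pooled t-test p) to 1e−8.
* **Size regression.** `size_regression()` is OLS of log Hg on total length
  per habit, with cluster-robust slope inference.
* **Type III partition.** `multiple_regression_type3()` fits
  `log(Hg) ~ location + habit + size + water` with sum-to-zero contrasts;
  each term's type III SS is the residual-SS increase from dropping it, and
  the partial R² divides that SS by the *total* SS of the response. With this
  definition the partials add up to the multiple R² exactly on orthogonal
  balanced designs (verified to 1e−8), which is the additivity the published
  variance partition displays. Market reports are excluded by default:
  their unrecorded water type is perfectly confounded with the market
  location level, and keeping them makes the model rank-deficient (the
  function detects and names aliased terms if forced).

## The synthetic generator

Because the 455-report database is available only on request, the generator
is a first-class, tested module, not a fixture. Individual log-Hg is

```
baseline + habit + ecosystem(habit) + water(habit) + slope(habit) * (length - genus mean) + N(0, sd)
```

and the report stores only the sample mean/SD/n of the exponentiated
individuals — exactly what a literature report provides. Defaults
(`default_paperlike_config()`) encode the study conditions: 455 reports over
46 studies; report sizes uniform on 3–30; carnivores above non-carnivores
(habit effect log 4 over a 0.08 µg/g baseline, making the pooled
concentration moments ≈ 0.5 ± 0.4 µg/g for carnivores and ≈ 0.125 ± 0.1 for
non-carnivores); lakes and hydroelectric reservoirs above rivers and markets
below for carnivores, markets elevated for non-carnivores; black water
highest for both habits; size slopes +0.03 (carnivores) and −0.09
(non-carnivores) per cm, the published regression coefficients. Covariate
allocation is balanced (uniform) because the real joint distribution of
covariates is unpublished; it is configurable. Reports typically cover one
size class, so each report draws a size *center* from the genus length
distribution and individual lengths scatter around it with a third of the
genus SD; this matches how length ranges arise across studies and keeps the
size effect identifiable from report means.

What the generator does **not** emulate: spatial/geostatistical structure,
temporal trends, the published per-genus mean table, study-level random
effects, or unbalanced covariate allocation. Passing recovery tests
therefore show that the chain is unbiased and correctly calibrated under
independent, balanced reports — not that any particular field dataset meets
those conditions.

## The exposure risk engine

The estimated weekly intake for one draw is

```
EWI = 7 * IR * C / BW     [µg / kg bw / week]
```

with IR the daily fish intake (g/person/day), C muscle Hg (µg/g w.w.) and BW
body weight (kg), compared against the JECFA provisional tolerable weekly
intake of 1.6 µg/kg bw/week. Scenario constants: consumption 67 g/day
(regional statistics, a deterministic point value), 149 ± 230 g/day (urban)
and 805 ± 1205 g/day (traditional communities); body weight 67.15 ± 13.5 kg.

All three inputs are modelled as independent log-normals matched to the
published arithmetic moments (`sigma² = log(1 + (sd/mean)²)`,
`mu = log(mean) − sigma²/2`). Log-normality is stated for body weight in the
source design; for consumption and concentration it is the only standard
two-parameter family consistent with positivity and an SD exceeding the mean
(805 ± 1205), so it is applied uniformly. A zero-truncated-normal family is
available behind `family = "truncnorm"` for sensitivity analysis (there the
stated mean/sd are parent parameters, so moments are not exactly preserved).

Because products and quotients of log-normals are log-normal,
`analytic_exceedance()` gives the exceedance probability in closed form
(`mu = log 7 + mu_IR + mu_C − mu_BW`, variances adding), and the Monte Carlo
(`run_monte_carlo()`, default 2^20 > 10^6 iterations) is continuously
validated against it within binomial sampling error. Exceedance uses the
strict inequality `EWI > PTWI`; the boundary carries no mass under
continuous families, and in the degenerate all-point-mass case ties count as
non-exceedance (with a 1e−12 relative guard for floating-point ties).

The habit-level concentration distributions used by the bundled scenarios
(`hg_reference_distributions()`: carnivores 0.5 ± 0.4, non-carnivores
0.125 ± 0.1 µg/g w.w.) are **synthetic stand-ins**: study-level pooled
moments were not published alongside the scenario constants. They anchor the
carnivore mean at the 0.5 µg/g regulatory reference with a CV of 0.8 typical
of between-fish variability, and they are deliberately coherent with the
synthetic generator's pooled output. Use `pooled_hg_by_habit()` on a real
database whenever one is available; the pipeline does exactly that.

## Numerical and design choices

* Box-Cox grid [−2, 2] step 0.01; argmax reported unrounded.
* CSV numerics written with 15 significant digits; round-trips are exact to
  at least 10.
* Monte Carlo default 2^20 = 1,048,576 iterations; a 10^4 floor guards
  against meaningless exceedance estimates (liftable for tests).
* Pipeline stage seeds derive from the master seed by fixed offsets (+1
  simulate, +2 reconstruct, +3 risk) and are recorded in the manifest.
* Test problem sizes: 100 seeded replicates of the 455-report configuration
  for effect recovery; 1000 replicates of a 3 × 20 null design for ANOVA
  calibration; 2 × 10^5–10^6 Monte Carlo iterations for oracle agreement —
  sizes at which the binomial/CI bounds used by the tests are sharp.

## Limitations

* No study-level random effects or inverse-variance weighting: the
  reconstruction follows the summary-resampling design it implements, not a
  formal random-effects meta-analysis.
* Independence of intake, concentration and body weight (one-dimensional
  Monte Carlo); no variability-vs-uncertainty separation.
* No speciation (total Hg is treated as the exposure-relevant quantity), no
  biokinetics, no selenium interaction.
* Dry-to-wet conversion requires an explicit moisture fraction; none is
  assumed.
* Flood-pulse seasonality and mapping are out of scope.
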