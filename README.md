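# fishmerc

Mercury in Amazon-basin fish and human dietary exposure, from report-level
literature summaries.

Published fish-mercury measurements usually arrive as summaries — a study
reports the mean, SD and sample size of muscle Hg (µg/g wet weight) for one
genus at one site — and the assembled meta-databases are rarely public.
`fishmerc` implements the full chain for working with such data:

1. **Data model & I/O** — a validated report-level schema (six regional
   genera with a fixed carnivore/non-carnivore mapping, ecosystem and
   Amazonian water types, sizes, provenance) with an exact CSV round-trip
   (`read_reports()`, `write_reports()`, `convert_dry_to_wet()`).
2. **Synthetic databases** — a seeded generator with known ground truth
   (`generate_reports()`, `default_paperlike_config()`: 455 reports / 46
   studies, carnivores elevated, lake/hydroelectric and black-water effects,
   habit-specific size slopes) so every downstream stage is testable.
3. **Pseudo-data reconstruction** — `reconstruct()` regenerates
   individual-level observations from each report's (mean, SD, n) under a
   normal model, with per-report RNG substreams and a positivity rule for
   log-scale modelling.
4. **Linear-model suite** — Box-Cox profile-ML transform selection,
   one-way ANOVA per feeding habit with Tukey–Kramer comparisons and a
   compact letter display, log-scale size regressions, and a four-term
   multiple regression with type III SS partial R²
   (`boxcox_select()`, `anova_oneway()`, `tukey_letters()`,
   `size_regression()`, `multiple_regression_type3()`).
5. **Exposure risk engine** — deterministic and probabilistic estimated
   weekly intake versus the JECFA provisional tolerable weekly intake:

   ```
   EWI = 7 · IR · C / BW        [µg · kg bw⁻¹ · week⁻¹],   PTWI = 1.6
   ```

   with intake IR (g/person/day), concentration C (µg/g w.w.) and body
   weight BW (kg) as independent moment-matched log-normals; a one-dimensional
   Monte Carlo (> 10⁶ iterations) estimates P(EWI > PTWI), validated against
   the closed-form log-normal exceedance (`deterministic_ewi()`,
   `run_monte_carlo()`, `analytic_exceedance()`, `scenario_grid()`).

`run_all()` chains simulate → reconstruct → models → risk from one flat
config file and writes CSV tables plus a reproducibility manifest;
`exec/fishmerc` exposes the same stages as a command line.

## Worked example

```r
library(fishmerc)

# a paper-like synthetic database with known effects
cfg <- default_paperlike_config(seed = 7)
gen <- generate_reports(cfg)
gen$reports
#> <fish_reports> 455 reports, 46 studies
#>   habits: carnivore=224, non_carnivore=231

ps <- reconstruct(gen$reports, seed = 11)
a  <- anova_oneway(ps, "ecosystem_type", habit = "carnivore")
tukey_letters(a)
#> <tukey_letters> alpha = 0.05
#>   hydroelectric   a
#>   lake            a
#>   river           b
#>   market          c

size_regression(ps, habit = "carnivore")
#> <hg_sizereg> [carnivore] log(Hg) = -1.718 +0.0248 * length; R2 = 0.050, p = 2.54e-06 (n = 3583, cluster SE)
```

Carnivores from lakes and hydroelectric reservoirs share the top letter
(highest Hg), rivers sit below, market fish lowest — the letter display
encodes exactly which Tukey-adjusted pairwise differences are significant at
α = 0.05. The size slope is positive for carnivores (+0.025 log-Hg per cm
here, recovering the injected +0.03) with a cluster-robust standard error,
because pseudo-observations within a report are not independent.

```r
# the most exposed scenario: traditional communities eating carnivorous fish
ref <- hg_reference_distributions()          # synthetic stand-in moments
sc <- exposure_scenario("traditional/carnivore",
                        consumption = consumption_presets()$traditional,
                        hg = c(0.5, 0.4), n_iter = 2e5, seed = 3)
run_monte_carlo(sc)
#> <risk_result> traditional/carnivore: deterministic EWI = 41.958 ug/kg bw/week
#>   P(EWI > 1.60) = 0.9697  (lognormal, n_iter = 200000, seed = 3)
#>   quantiles:  q2.5=1.433 q25=7.653 q50=18.592 q75=45.024 q97.5=241.863
analytic_exceedance(sc)
#> [1] 0.969566
```

A deterministic weekly intake of ~42 µg/kg bw — 26 times the tolerable
intake — and ~97% of Monte Carlo draws above it: the simulation and the
closed-form oracle agree to Monte Carlo error.

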