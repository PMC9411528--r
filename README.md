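# trophoscale

Predator–prey biomass scaling in complex food webs.

Across ecosystems, predator biomass `y` tends to scale with the biomass of
its prey `x` as a power law `y = c·x^k` with `k` below one and often near
3/4 — biomass pyramids get more bottom-heavy as they grow. `trophoscale`
brings this analysis to *complex, omnivorous food webs*, where prey are
shared among many predators and trophic height is non-integer. It is
written for community ecologists working with node/link food-web tables
(taxon body masses, numerical abundances, directed feeding links).

The package implements the full workflow:

* **Food-web data model and I/O** — a documented two-table CSV dialect
  (nodes + links, multiple webs per file, an optional YAML column mapping
  for foreign exports), with validation and bit-exact round-tripping.
* **Trophic metrics** — prey-averaged trophic level `TL_i = 1 +
  mean(TL_prey)` via an exact linear solve (valid for feeding loops),
  omnivory (variance of prey trophic levels), generality, vulnerability,
  and the log10 predator–prey body-mass ratio (PPmR).
* **Biomass tables** — per-predator *available prey biomass* that divides
  each prey node's biomass by its vulnerability (the number of consumers
  feeding on it), so shared prey are split conservatively; plus per-web
  totals for across-web analysis. Filters: predators above trophic level
  2.5, webs with ≥ 5 predators spanning ≥ 1 decade of prey biomass.
* **Scaling models** — within-web linear mixed-effects fits (random
  slope/intercept per web, AIC + likelihood-ratio model selection, REML
  refit, Wald CIs; lme4/lmerTest), trait-augmented models with
  Satterthwaite F-tests, per-web OLS slopes, across-web ANCOVA with a
  common-slope F-test, and a prey body-mass diagnostic.
* **Synthetic generator** — layered, niche-ordered webs whose consumer
  biomasses follow the power law bottom-up with known per-web `(k_i,
  c_i)`, so every estimator can be verified by parameter recovery.

## Worked example

```r
library(trophoscale)

ds <- generate_dataset(synthetic_config(n_webs = 10, seed = 42))
report <- run_pipeline(webs = ds)
print(report)
#> <pipeline_report> status: ok
#>   webs: 30 in, 27 within-web, 27 across-web
#>   within-web records: 491
#>   within-web k_bar = 0.766 (0.711 to 0.821)
#>   across-web k_bar = 0.845 (0.480 to 1.211)

report$fits$within
#> <scaling_fit> within-web LME power law
#>   k_bar = 0.7663 (95% CI 0.7113 to 0.8213)
#>   c_bar = -0.5052
#>   k[freshwater] = 0.7460 (0.6566 to 0.8353)
#>   k[marine] = 0.7831 (0.6906 to 0.8755)
#>   k[terrestrial] = 0.7702 (0.6616 to 0.8788)
#>   sigma_res = 0.2955
#>   R2 marginal = 0.597, conditional = 0.816
```

Thirty synthetic webs were generated with a mean exponent of 0.75; three
fail the one-decade prey-biomass-range filter. The mixed model recovers
`k_bar` = 0.766 with a 95% interval covering the truth, per-ecosystem
slopes agree, and the residual SD (0.296) matches the generating noise
(0.3). `biomass_gain(0.71)` returns 63.6: at `k` = 0.71 a doubling of
prey biomass raises predicted predator biomass by ~64%, and
`predator_fold_change(0.71, 5)` ≈ 3.1 — a roughly three-fold predator
increase per five-fold prey increase.

Real data enter through `read_web_tables("nodes.csv", "links.csv")`
(columns `web_id, ecosystem_type, node_id, taxon_name, body_mass_g,
abundance_per_m2, is_basal, is_aggregate` and `web_id, consumer_id,
resource_id`), or via `run_pipeline(nodes_csv, links_csv, out_dir = ...)`
which also writes the metrics, record tables, per-web slopes and a JSON
report.

See `vignettes/predator-prey-scaling.Rmd` for the model, its assumptions,
the generator design and the package's numerical choices.

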