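---
title: "Quantifying predator-prey biomass scaling in complex food webs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying predator-prey biomass scaling in complex food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophoscale)
```

## The scientific problem

The ratio of predator to prey biomass is a basic descriptor of trophic
structure. Across many systems, total predator biomass $y$ scales with the
biomass of its prey $x$ as a power law,

$$ y = c\,x^{k}, $$

with $c$ a normalisation constant and $k$ a dimensionless exponent.
Exponents below one mean that biomass pyramids become increasingly
bottom-heavy as prey biomass grows; empirical syntheses repeatedly find
$k$ near $3/4$. Testing whether this holds inside *complex, omnivorous
food webs* — rather than between neatly separated trophic levels —
requires (i) per-node biomass estimates, (ii) a rule for how shared prey
biomass is apportioned among the predators that feed on it, and (iii)
regression machinery that respects the grouping of predators within webs.
`trophoscale` implements this workflow end to end, together with a
synthetic food-web generator whose generating parameters are known, so
every stage of the pipeline can be verified by parameter recovery.

## Data model

A `food_web` couples a node table (taxon, mean individual body mass in g
dry weight, numerical abundance per m², basal and aggregate flags) with a
directed feeding-link table (consumer → resource) under a web id and an
ecosystem-type label (freshwater, marine, terrestrial). Node biomass is
abundance × body mass (g/m²). Links are de-duplicated on load;
cannibalistic self-links are retained in the data but excluded from every
trophic computation, because the trophic-level recursion is otherwise
ill-defined. The `is_basal` flag is reconciled with the link structure on
load (basal ⇔ no prey), with a warning when the two disagree.

## Trophic metrics

* **Trophic level.** $TL_i = 1 + \mathrm{mean}(TL_{\text{prey}(i)})$ with
  basal resources fixed at 1. With equal diet weights $1/g_i$ over each
  consumer's $g_i$ prey this is the linear system $TL = 1 + D\,TL$ with a
  row-stochastic diet matrix $D$; we solve it exactly with a dense LU
  factorisation rather than iterating, which remains valid for webs with
  feeding loops provided every loop drains to a basal resource. A loop
  with no path to a basal node makes the system singular; the error then
  names the offending strongly connected component. Equal weights are the
  natural default when diet proportions are unknown.
* **Omnivory** is the variance of a predator's prey trophic levels. We use
  the population denominator (divide by the number of prey): the prey set
  is the complete set of links, not a sample. The sample denominator is
  available via `denominator = "sample"`; single-prey specialists have
  omnivory 0 either way.
* **Generality / vulnerability** are feeding out-/in-degrees with
  self-links excluded. Vulnerability counts *all* consumer nodes
  regardless of their biomass, since a zero-biomass consumer still
  represents a feeding channel.
* **PPmR** is $\log_{10}$ of predator body mass over the unweighted
  arithmetic mean of its prey's body masses. A geometric-mean option
  exists (`prey_mass_mean = "geometric"`); the arithmetic mean is the
  default reading of "mean prey body mass".

## From webs to analysis tables

**Within-web records.** For each predator the *available prey biomass* is
the sum over its prey of prey biomass divided by prey vulnerability, so a
prey shared by $v$ consumers contributes $1/v$ of its biomass to each.
This conserves biomass exactly: summed over all consumers, the shares of
every consumed prey reassemble its standing stock (a property the tests
check to relative error $10^{-9}$). The unadjusted variant (full prey
biomass to every consumer) is exposed as `adjust_vulnerability = FALSE`
for sensitivity analysis.

Predators enter the within-web table when their prey-averaged trophic
level exceeds `tl_cutoff` (default 2.5, i.e. feeding mostly on animal
prey; 3 is the usual sensitivity setting) and they are not coarse
taxonomic aggregates. Webs are retained when they keep at least
`min_predators = 5` records spanning at least `min_x_range_decades = 1`
decade of available prey biomass — below either threshold a per-web slope
is not meaningfully estimable. The decade filter is applied to the fitted
covariate (per-predator available prey biomass), not to raw node
biomasses, because it is the regressor's spread that limits slope
estimation. Records with non-positive biomass on either axis are dropped
with a logged count before the log10 transforms.

**Across-web summaries** total the biomass of all qualifying predators
(aggregates *included* at this level) and the combined biomass of the
union of their prey, each prey counted once at full biomass ("combined
biomass of prey" is a node-set total; a vulnerability-shared variant is
available as `across_prey_shared`). A node that is both predator and prey
contributes to both totals — omnivorous webs make the two sets overlap
and de-overlapping them would misstate either stock. Mean prey body mass
over the same prey union is recorded for the prey-size diagnostic,
unweighted by default with an abundance-weighted switch.

## Statistical models

**Within webs** the records are grouped by web, and both the slope and
the intercept plausibly vary between webs, so we fit linear mixed-effects
models (`lme4`) of $\log_{10} y$ on $\log_{10} x$ with web-level random
effects, selected top-down in two stages:

1. with full fixed effects ($\log_{10}x \times$ ecosystem type), the
   random structures {correlated random slope + intercept, uncorrelated,
   intercept-only} are compared by AIC under REML. A singular winner
   falls back to the next-simpler structure with a warning.
2. under the chosen random structure, the ecosystem × slope interaction
   (and then the ecosystem main effect) is tested by likelihood-ratio
   tests on ML fits at $\alpha = 0.05$.

The selected model is refitted by REML; the mean exponent $\bar k$ is its
slope with a 95% Wald interval (profile intervals are slower and in our
simulations indistinguishable at these sample sizes; Wald is the
default). Per-ecosystem slopes are always reported from the
full-interaction REML fit, resolved from treatment contrasts to absolute
slopes with delta-method standard errors. If the interaction is retained,
$\bar k$ is the unweighted average of the per-ecosystem slopes.

*Variance explained.* For mixed models a single $R^2$ is ambiguous, so we
report both the marginal (fixed effects only) and conditional (fixed +
random) variance fractions, computing the random-effect variance over the
observed covariate values (the random-slope extension of the usual
variance-decomposition $R^2$). Comparisons before/after adding traits
should use the same flavour.

**Predator traits.** PPmR and omnivory (each × ecosystem type) are added
as fixed effects to the selected model. Candidate predictors that are
constant or pairwise correlated with $|r| > 0.7$ against the prey-biomass
covariate or an already-kept trait are dropped with a warning — strongly
collinear terms would render the partial coefficients uninterpretable.
Term significance uses F-tests with Satterthwaite denominator degrees of
freedom (`lmerTest`); if the Satterthwaite computation fails the code
falls back to likelihood-ratio tests with a notice. Partial residuals
(residuals plus the trait term's contribution) are returned for plotting
trait panels.

**Across webs** each web contributes one point, so mixed models are
unnecessary: analysis of covariance (`lm`) of log total predator biomass
on log total prey biomass × ecosystem type. The ecosystem × slope
interaction is tested by the F-test of the separate-slope model against
the common-slope (additive) model; the common slope is reported as
$\bar k$ with its t-based interval. The prey body-mass diagnostic re-runs
the same machinery with log mean prey body mass as the response: a slope
near 1 would implicate changing prey size, a slope near 0 changing prey
density. Outlying webs for this diagnostic are supplied by id — such
outliers are a data annotation (e.g. streams naturally lacking fish), not
something computable from the tables. All fits use ordinary least squares
(type 1 regression) for comparability with prior syntheses.

**Per-species scaling** (`fit_species_across_webs`) fits the OLS power
law of one predator species' biomass against its available prey biomass
across the webs it occupies (at least 5 required), e.g. to detect species
that escape the community-level power law.

## The synthetic generator

`generate_dataset()` emulates the *structure* of multi-ecosystem food-web
collections, not any particular dataset:

* **Topology.** Niche-ordered acyclic webs with `n_basal = 8` basal
  resources and consumers allocated to trophic layers 2–4 in fractions
  0.40/0.35/0.25 of 35–45 nodes per web; each consumer eats at least one
  node of the layer below and samples further prey from lower layers
  (adjacent layer favoured 3:1), with mean generality set from a
  connectance target of 0.10 — all within the ranges typical of published
  community webs. Three layers of consumers guarantee predators above the
  2.5 trophic-level cut-off. An optional loop-injection flag closes one
  upward feeding cycle for stress-testing the trophic-level solver.
* **Biomass.** Basal biomasses are log-uniform over 4 decades (centred at
  10 g/m²), spanning the kind of cross-site biomass gradient the analysis
  needs. Consumers are then filled in bottom-up:
  $\log_{10} y = c_i + k_i \log_{10} x + \beta_{P}\,\mathrm{PPmR} +
  \beta_{O}\,\mathrm{Omn} + \varepsilon$, where $x$ is exactly the
  vulnerability-adjusted available prey biomass the pipeline later
  reconstructs, $(k_i, c_i)$ are per-web draws around
  $(\bar k, \bar c) = (0.75, -0.5)$ with SDs $(\sigma_k, \sigma_c) =
  (0.05, 0.3)$, correlation $\rho = 0$, and
  $\varepsilon \sim N(0, \sigma_{res} = 0.3)$. Because the generating
  covariate equals the fitted covariate, parameter recovery is a sharp
  test rather than an approximation. Trait coefficients default to zero
  and can be injected.
* **Body size.** $\log_{10}$ body mass climbs 2 decades per trophic level
  from a basal mean of $10^{-6}$ g with 0.25 decades of lognormal
  scatter, giving realistic PPmR distributions; abundance is biomass /
  body mass.
* **Reproducibility.** One master seed; per-web substreams are drawn from
  it by counter, so each web is identical regardless of generation order,
  and identical config + seed reproduce the files byte-for-byte.

What the generator does *not* emulate: taxonomy, gut-content link
weights, sampling error in abundance estimates, spatial structure, or any
across-web relationship between totals — the across-web exponent of a
synthetic batch is an emergent property of aggregation, not a dialled
parameter. Passing recovery tests therefore demonstrates that the
estimators are correct for data generated by the model they assume; they
cannot certify field data, where diet weights, detection biases and
incomplete basal coverage intervene.

## Numerical and degenerate-case choices

* Trophic levels use an exact dense solve ($O(S^3)$, trivial at
  community-web sizes) rather than fixed-point iteration; the tests
  cross-check both on 1000 random webs at $10^{-10}$.
* Noise-free (exactly collinear) record tables cannot be fitted by
  `lmer` (zero residual variance); `fit_within_lme()` detects pooled
  residual SD below $10^{-8}$ and returns the exact pooled-OLS fit with
  zero variance components, flagged in the `kind` string.
* A single web, or a single ecosystem type, degrades gracefully: OLS
  replaces the mixed model, and the interaction test is skipped with a
  note.
* Webs whose covariate has zero variance are skipped in per-web OLS with
  a message; rank-deficient ANCOVA designs raise a typed error.
* Ecosystem type is an unordered factor with alphabetical reference
  level; reported per-ecosystem slopes are always resolved to absolute
  values.
* Optimiser settings are `lme4` defaults with derivative checks disabled
  (the fits are refitted anyway during selection); convergence and
  singularity conditions are handled, not silenced, via the fallback
  ladder described above.

## Problem sizes used by the test-suite

Deterministic properties run on webs of 5–45 nodes; oracle equivalence on
1000 random webs; stochastic parameter recovery on 50 Monte-Carlo
replicates of 30 webs × ~15 qualifying predators each (mean recovered
$\hat{\bar k}$ within ±0.02 of 0.75, interval coverage ≥ 0.88). These
sizes make the whole suite run in a couple of minutes while leaving the
Monte-Carlo standard error of the recovery check well below its
tolerance.

## Known limitations

* Equal diet weights throughout: with real interaction strengths both
  trophic levels and the prey-biomass apportioning would change; the
  package has no weighted-link support.
* Basal-resource biomass is not part of the analysis; the within-web
  table deliberately starts above trophic level 2.5.
* The choice between population/sample omnivory variance and
  arithmetic/geometric prey-mass means is conventional; both are config
  switches and the defaults are stated above.
* The across-web exponent of synthetic data need not equal the within-web
  generating exponent (aggregation is not slope-preserving), so
  across-web checks are structural (correctness of totals, F-tests,
  intervals) rather than recovery of a known slope.

## A minimal run

```{r example, eval = FALSE}
ds <- generate_dataset(synthetic_config(n_webs = 10, seed = 42))
report <- run_pipeline(webs = ds)
report$fits$within
```
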