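---
title: "Methods: city-level livestock methane inventories with dynamic emission factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: city-level livestock methane inventories with dynamic emission factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livestockCH4)
library(data.table)
```

## The problem

Livestock are the largest anthropogenic methane source. Bottom-up
inventories estimate emissions as *activity data × emission factors*
(EF): head counts of each livestock category multiplied by the methane
each head emits per year. Constant national EFs miss the strong spatial
and temporal heterogeneity of animal body weight, milk productivity,
manure handling and climate, so this package builds *dynamic* EFs from
region-year animal traits and computes a city-resolved inventory with
two pathways — enteric fermentation (rumen digestion) and manure
management (anaerobic decomposition of stored manure) — plus Monte Carlo
uncertainty bounds.

Twelve categories are covered. Ruminants: dairy cattle, nondairy cattle,
buffalo, sheep, goats, camels. Nonruminants: swine, horses, donkeys,
mules, poultry, rabbits. Cattle and buffalo are split into mature
females / young / others, sheep and goats into mature females / others;
the rest are whole herds. Dairy cattle, nondairy cattle, buffalo, sheep,
goats and swine carry region-specific Tier 2 pathways; the minor species
use fixed Tier 1 factor pairs from provincial guidelines.

## Enteric fermentation model

For Tier 2 ruminants the EF follows from daily gross energy intake GE
(MJ day⁻¹) and the methane conversion factor Ym (% of GE lost as
methane):

$$EF = \frac{GE \cdot (Y_m/100) \cdot 365}{55.65}
\qquad \text{(kg CH}_4\ \text{head}^{-1}\ \text{yr}^{-1}\text{)}$$

with 55.65 MJ kg⁻¹ the energy content of methane. GE is assembled from
net-energy components:

$$GE = \frac{(NE_m + NE_a + NE_l + NE_{work} + NE_p)/REM +
(NE_g + NE_{wool})/REG}{DE/100}$$

* `NE_m = cf · W^0.75` — maintenance; `cf` 0.322 (cattle/buffalo), 0.386
  for lactating females, 0.217/0.236 for sheep and goats.
* `NE_a = ca · NE_m` — activity; `ca` 0 (stall), 0.17 (pasture), 0.36
  (large-area grazing).
* `NE_l = milk_daily · (1.47 + 0.40 · fat%)` — lactation, mature females
  only.
* `NE_p = cp · NE_m · pregnancy_fraction` — pregnancy, mature females
  only (`cp` 0.10 cattle, 0.077 sheep/goats).
* `NE_g = 22.02 · (W/(c·MW))^{0.75} · WG^{1.097}` — growth, young
  animals only (MW = mature weight, WG = daily gain in kg).
* `NE_wool = 24 · wool_yield / 365` — fibre production.
* `NE_work` is always zero: draft-animal work is excluded because draft
  animals are poorly counted and largely mechanised away.

REM and REG are the standard empirical fractions of digestible energy
available for maintenance-type and growth-type uses; both are functions
of the digestibility DE (%), valid on DE ∈ [45, 85]. DE enters GE as a
*fraction* (DE/100): with percent units the magnitudes would be off by
100, so the dimensional form is fixed in code and tested.

Dairy cattle are the exception: official sources do not record their
body weight, so the EF is regressed on annual milk production per head,
`EF = 30.8 · production^0.2 − 53.6` with production in kg head⁻¹ yr⁻¹.
Daily units would give negative factors — the function refuses
production values in the non-positive-EF domain, pointing at the unit
convention. All dairy subclasses receive the regional regression factor,
since the regression is the only dairy pathway defined. Swine are Tier 2
for manure but have no enteric energy pathway; they carry a configured
constant (default 1.0 kg head⁻¹ yr⁻¹).

## Manure management model

Per-head manure EFs combine volatile-solids excretion with the degree of
anaerobic decomposition:

$$VS_{daily} = VS_{rate} \cdot \frac{AM}{1000}, \qquad
EF = 365 \cdot VS_{daily} \cdot B_0 \cdot \rho \cdot
\sum_S \frac{MCF_{S,k}}{100} \cdot Management_S$$

`VS_rate` is kg VS per 1000 kg animal mass per day, `AM` the
(region-year, subclass-specific) live weight, `B0` the maximum methane
potential of the category's manure (m³ CH₄ per kg VS), ρ the methane
density converting volume to mass, `Management_S` the fraction of manure
handled in system S (liquid/slurry, solid storage, daily spread,
pasture, dry lot, digester, lagoon, other), and `MCF_{S,k}` the percent
of `B0` realised in system S under climate class k.

Two notational wrinkles in the source formulation are resolved
deliberately:

* **Single annualisation.** Writing the ×365 both in the VS equation and
  in the EF equation would annualise twice and inflate EFs ~365-fold;
  the implementation keeps VS daily and applies 365 once.
* **Methane density.** The printed constant 0.067 is an order of
  magnitude below the physical density of methane (0.67 kg m⁻³, the
  IPCC value). The default is 0.67; `constants.methane_density_kg_per_m3: 0.067`
  in a config reproduces the literal constant if wanted.
* **No double-weighting.** The emission summation re-lists VS and the
  management fraction outside the EF; since both already live inside the
  EF, emissions are computed as N·EF.

Climate classes are assigned from city annual mean temperature with
half-open bins: cool (−∞, 15), temperate [15, 25), warm [25, ∞) °C,
boundary assigned upward. The exact bin edges of the source's
supplementary material are unavailable; these IPCC-style three-class
bins are a declared default, as are the shipped MCF values (chosen
non-decreasing cool → warm, which the tests verify end-to-end).

## Lifespan-weighted accounting

Both the stock population (alive at year end) and the slaughtered
population (raised and killed within the year) emit during the year.
Each head contributes `EF · ALS/12`, where the average lifespan ALS is
the number of months the animal emits within the calendar year: 12 for
stocked cattle but 5.6 for stocked sheep, and shorter spans for
slaughtered animals (defaults: cattle and swine 6, sheep/goats 3,
poultry 2 months), which encodes the assumption that slaughter is spread
uniformly through the year. The source's full ALS table is unavailable;
all values are explicit config defaults with the invariant
ALS(slaughtered) ≤ ALS(stock) enforced at load time. Emissions are
reported in Gg CH₄ yr⁻¹ per (city, year, category, pathway) and
aggregate exactly to province and national series.

## Gap-filling

A few cities lack breeding records entirely. For those, the slaughtered
population is reconstructed from meat production divided by carcass
weight, and the stock population by inverting the slaughter rate
(slaughtered/stock). The rate is resolved in priority order: the same
city's other years (slaughter rates are stable within a city), then
same-province cities in the same year ("adjacent" is read as
same-province, since no adjacency graph is shipped), then the province
mean over all years. Head counts round half-up to integers. Filled rows
are flagged `gapfilled`; observed rows are never touched.

Missing trait years are filled multiplicatively:
`fill_body_weight_series()` interpolates geometrically between observed
anchors and extends the series ends with the mean annual log change
rate; a single observation is held constant. Whether the source's
change-rate fill is additive or multiplicative is not stated;
multiplicative is this package's choice (weights are positive,
rates compound).

## The synthetic world

`generate_activity_panel()` and friends stand in for the compiled
statistical-yearbook panel, with defaults that state the world once:

* 347 cities in 31 provinces, 2010–2020 — reproducing the published
  record structure (3817 city-year cells; 7634 ruminant/nonruminant
  records).
* Lognormal per-category herd sizes (e.g. median 10⁶ swine, 8×10⁴
  nondairy cattle per city) — strictly positive and heavy-tailed like
  municipal herd statistics; year dynamics follow a multiplicative
  random walk with |log step| ≤ 0.3.
* 5% of cities blanked (below the "less than 5% of the sample"
  statement), with meat-production rows retained so the gap-fill path is
  always exercised; meat = slaughtered × carcass weight exactly, making
  parameter recovery testable to rounding.
* Body weights vary smoothly (adjacent-year ratio within [0.96, 1.04]),
  northern provinces are 15% heavier (the documented north–south cattle
  weight gradient), dairy milk yields stay within 3000–9000 kg head⁻¹
  yr⁻¹.
* Province base temperatures follow a deterministic north-cold /
  south-warm gradient (5–28 °C ± jitter) so all three climate classes
  are populated by construction for any seed once a panel has a handful
  of provinces.
* Three activity-data variants emulate discrepant statistical sources:
  variant 1 is the panel itself; variants 2–3 add mean-preserving
  multiplicative lognormal noise at the stated discrepancy CV.

What the generator does *not* emulate: the true spatial distribution of
Chinese livestock, correlations between categories, reporting-system
changes, or administrative boundary revisions. A green test therefore
establishes that the pipeline's accounting, formulas and error
propagation are correct under the stated statistical structure — not
that the shipped default parameters reproduce any published national
total.

## Monte Carlo uncertainty

Activity data are perturbed with uniform draws, EFs with normal draws
truncated at zero (resampled), each parameterised by a per-category CV;
10,000 simulations; the 95% interval is the empirical 2.5/97.5
percentile pair of national annual totals. Choices worth stating:

* **Uniform half-width √3·CV·mean**, so the uniform draw's true CV
  equals the stated CV (the width convention is not given in the
  source).
* **Systematic perturbations**: one factor per category per simulation,
  shared across cities. Independent city-level draws would average out
  across ~350 cities and collapse the national interval; yearbook biases
  are systematic, and the shared convention yields intervals of the
  ±20% order reported for this kind of inventory.
* **Fast path by bilinearity**: emissions are bilinear in head counts
  and EFs, so each simulation's national total is the base
  per-(year, category) contribution scaled by the two factors. This is
  an algebraic identity, not an approximation; the test suite checks
  equality (1e-9) against literally re-running `compute_emissions()` on
  perturbed inputs.
* The activity-data CV estimated from the three variants is the mean
  absolute deviation from the cell mean, normalised by that mean and
  head-count-weighted across cells; the pairwise-difference reading is
  available via `method = "pairwise"`.

## Numerical and interface choices

* DE domain enforced at [45, 85]% — REM/REG are fitted there and the
  reciprocal terms misbehave outside.
* Exports are CSV at full precision: rounding to a fixed number of
  significant digits would break the partition identities (categories
  sum to national totals, pathways sum to totals) that the exported
  files are tested to satisfy at 1e-9. No XLSX writer is available in
  the supported dependency set; XLSX *input* is accepted via readxl when
  installed.
* Parameter configs are YAML (JSON accepted), overlaid on the shipped
  defaults so a config states only what it changes; a full round-trip
  reproduces the parameter set field-by-field.
* All generators restore the caller's RNG state; determinism is per
  explicit seed, never per session.
* Head counts are rounded half-up — yearbook head counts are integral.

## Known limitations

* Shipped trait, MCF, lifespan and CV values are IPCC-style defaults,
  not the source's (unavailable) supplementary tables; absolute emission
  levels from the default synthetic world are plausible in magnitude but
  not comparable to published national totals.
* Sheep/goat residual classes accrue no growth energy by default
  (configurable via `energy.others_grow`).
* No nitrous oxide, no CO₂-equivalent conversion, no gridded
  disaggregation, no external-inventory comparison.
* Tier 1 manure factors ignore climate class by construction.
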