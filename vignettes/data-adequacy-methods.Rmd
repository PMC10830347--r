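---
title: "Quantifying species-level data adequacy in checklist-based citizen science"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying species-level data adequacy in checklist-based citizen science}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adequacy)
library(dplyr)
```

## The problem

Citizen-science platforms such as eBird and Birdata produce enormous volumes
of semi-structured checklist data: survey events at a place and time on which
an observer reports the species they detected. Before such data can be used
to monitor a species — to model its distribution, track its abundance, or
inform its conservation assessment — an analyst needs to know whether the
data for *that species* are adequate: has its range been surveyed, has the
species actually been recorded across that range, and is the survey effort
spread evenly enough to support inference? This package computes three
per-species answers to those questions on a regular geographic grid, together
with the filtering, temporal and trait-modelling machinery around them.

## The three metrics

Everything is computed on a regular longitude/latitude grid of square cells
of side `cell_size` degrees (the *grain*; 1 degree by default). A species'
**range** is the set of grid cells its mapped distribution overlaps with
positive area. All three metrics are cell-count based, so cell areas never
enter the definitions and no projection is needed.

**Inventory completeness (IC)** of a cell is the proportion of the species
richness expected there (from stacked range maps) that has been recorded
there:
\[ \mathrm{IC}(c) = \frac{|\text{species observed in } c|}{|\text{species mapped in } c|}. \]

**Mean inventory completeness (MIC)** of a species is the unweighted mean of
IC over all cells of its range — how adequately surveyed the species' range
is. Unsurveyed range cells contribute IC = 0: dropping them would make an
unsurveyed range look perfectly known, the opposite of what the metric must
measure.

**Total range completeness (TRC)** is the proportion of a species' range
cells holding at least one record of the species — how much of the range the
data actually cover.

**Checklist spatial bias (CSB)** measures how evenly survey effort is spread
over the species' range. With \(p_c\) the observed share of checklists in
range cell \(c\) (of \(n\) cells) and \(e_c = 1/n\) the uniform null,
the default divergence is the total-variation distance
\[ H = \tfrac{1}{2} \sum_{c} |p_c - e_c|, \qquad \mathrm{CSB} = 1 - H, \]
equivalently the Schoener-type proportional similarity
\(\sum_c \min(p_c, e_c)\). CSB is 1 exactly when effort is uniform, falls to
\(1/n\) when all effort sits in one cell of an \(n\)-cell range, and is
*undefined* (not zero) when a species has no in-range checklists at all —
there is no effort distribution to compare. The divergence is a strategy
hook: any function mapping a vector of per-cell checklist counts to a
divergence in \([0, 1)\) can be passed as `h_fun` to `compute_adequacy()`,
so an alternative bias statistic changes one argument, not the pipeline.

Because the range is the unit of reference, MIC and TRC can only grow as
records accumulate, while CSB can worsen: concentrating new effort into
already well-surveyed cells drags the observed effort distribution away from
uniform even as completeness rises. The cumulative series tests encode
exactly this asymmetry.

## Filtering rules

`filter_checklists()` and `filter_observations()` implement the standard
cleaning sequence for checklist data, each stage logged in a provenance
table:

1. non-complete checklists (incidental observations) are dropped;
2. checklists outside the grid extent are dropped;
3. duplicate copies of shared checklists (same `group_id`) are reduced to
   one, keeping the lexicographically smallest checklist id so the choice is
   deterministic;
4. observations of species flagged exotic, vagrant, extinct or marine are
   removed (flags come from a status list);
5. observations outside the species' gridded range are treated as vagrant
   records and removed.

Two deliberate choices: no effort-variable filtering (duration, distance) is
performed, and checklists emptied of all observations by stages 4–5 are
**retained** — they are still survey effort, and both the IC denominator
logic and the CSB effort counts need them. Records from all years are kept
by default; year bounds are configuration.

## Temporal series

`cumulative_series()` recomputes the metrics on all checklists up to each
year; `annual_series()` on each year alone. `summarize_series()` reduces a
series to the cross-species median and 5th–95th percentiles (linear
interpolation between order statistics) per year and metric, counting how
many species had a defined value — species-years with undefined CSB are
excluded from that year's CSB summary rather than imputed. The default
period is 1980–2022; both bounds are configuration, and any plotting window
is a presentation choice, not a computation one.

## Trait models

`run_all_models()` fits one ordinary-least-squares model per metric on seven
species traits: IUCN threat status (dummy-coded with CR as the reference
level; category order LC < NT < VU < EN < CR), taxonomic uniqueness, body
mass, average count (mean of the numeric counts in the data, present-only
records excluded), range size (cells), species density, and mean human
population density over the range. The six continuous predictors are
natural-log transformed — the base only rescales coefficients, not
inference — so they must be positive; non-positive or missing values exclude
the species. Exclusion is listwise with recorded reasons and shared across
the three fits, so all models see an identical species set. Raw p-values are
reported with the conventional star cut-offs (<.001, <.01, <.05); with 30
coefficients across three models a reader may prefer their own multiplicity
correction, so none is imposed. Fits are `stats::lm()` underneath; `tidy()`
and `glance()` return the coefficient table and fit statistics.

## The synthetic world generator

Real eBird/Birdata exports are large, licensed and external, so the package
carries a generator (`world_config()`, `gen_world()`, `gen_checklists()`)
that emulates the statistical structure of the inputs with known ground
truth: connected species ranges grown by seeded random accretion (plus
optional single-cell island endemics), a smooth-gradient-plus-noise human
density surface, lognormal/categorical traits, and checklists placed with
probability proportional to `human_density^gamma` — `gamma = 0` is uniform
effort, larger values concentrate effort where people are, which is the
mechanism behind real-world spatial bias. Detection is an independent
Bernoulli per checklist and present species; counts are truncated-at-1
Poisson with a configurable present-only fraction; configurable fractions of
incomplete, shared-duplicate and out-of-range (vagrant) records exercise
every filter stage. All outputs are pure functions of the configuration,
seed included.

Default conditions (a 10 × 10 one-degree grid, 20 species with log-uniform
range sizes of 1–40 cells including 2 islands, 500 checklists over
2000–2009, `gamma = 1`, detectability uniform on 0.3–0.9, 10% present-only,
5% incomplete, 5% shared) were chosen once as a desk-scale analogue of a
regional citizen-science dataset. What the generator does *not* emulate —
real coastline geometry, observer heterogeneity, seasonal phenology,
taxonomic confusion — bounds what green tests mean: they verify the metrics,
filters and models, not the ecological realism of any particular dataset.

## Numerical and geometric choices

- Cells are half-open, lower-inclusive intervals; points exactly on the
  global maximum boundary fold into the last cell, making assignment total
  and deterministic. A forward tolerance of 1e-9 cell widths keeps points
  that sit numerically *on* an interior boundary (e.g. 0.6/0.2) in the cell
  the exact arithmetic would give.
- Range polygons are rasterized by clipping each ring against candidate cell
  rectangles (Sutherland–Hodgman) and measuring the clipped area (shoelace);
  a cell joins the range only if the intersection area exceeds 1e-10 of a
  cell — boundary touches do not count, avoiding spurious single-point
  inclusions along shared edges. Holes subtract their clipped area.
  Pre-gridded cell-list CSVs bypass geometry entirely.
- Percentiles use linear interpolation between order statistics
  (`quantile(type = 7)`).
- OLS rank deficiency is an error naming the collinear terms, not a silent
  `NA` coefficient.

## Problem sizes in the test-suite

The property suites run on randomly drawn worlds of at most 10 × 10 cells,
20 species and a few hundred checklists — large enough to hit every code
path (empty cells, undefined CSB, single-cell ranges, shared duplicates) and
small enough to compare against brute-force oracles exactly. The OLS
recovery study uses 200 replicates at n = 500; the grain-sensitivity run
re-grids one fine-grain world at 2.0, 1.0, 0.5 and 0.2 degrees and checks
that species rankings by each metric stay positively rank-correlated, the
desk-scale analogue of a grain-robustness check.

## A worked example

```{r example, eval = FALSE}
cfg <- world_config(seed = 1, effort_bias_exponent = 2)
sim <- simulate_world(cfg)
adq <- compute_adequacy(sim$table, sim$world$ranges, cfg$grid)
summary(adq$csb)

pts <- cumulative_series(sim$table, sim$world$ranges, cfg$grid, 2000:2009)
plot_series(summarize_series(pts))

traits <- assemble_traits(
  dplyr::select(sim$world$traits, species, threat_status,
                taxonomic_uniqueness, body_mass, species_density),
  sim$table, sim$world$ranges, sim$world$human_density)
models <- run_all_models(traits, adq)
glance(models)
autoplot(models)
```

## Known limitations

- The spatial-bias null is uniform over range *cells*, not area-weighted;
  at coarse grain near coasts this differs from a uniform-over-land null.
- Polygon holes are supported but nested multi-level (island-in-lake)
  geometries are not.
- Shared-checklist deduplication keys on `group_id` only; fuzzy
  spatio-temporal duplicate detection is out of scope.
- Taxonomy is assumed already reconciled to one species-code namespace.
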