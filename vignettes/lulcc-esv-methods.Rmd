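---
title: "Land-use change, Markov-CA simulation, and ecosystem-service valuation with luccesv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-use change, Markov-CA simulation, and ecosystem-service valuation with luccesv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luccesv)
```

## The problem

Regional land systems are commonly observed as a short series of categorical
land-cover maps (here: cropland, forestland, grassland, wetland, waterbody,
construction land, unused land) classified from satellite imagery a decade
apart. `luccesv` implements the standard analysis chain built on such maps:

1. **Change metrics** — cross-tabulate each pair of dates into a transition
   matrix of converted areas and summarize it with annualized dynamic
   degrees.
2. **Markov-CA simulation** — estimate a Markov transition kernel from the
   latest observed pair, project per-class areas forward, and allocate the
   projected areas in space with a cellular automaton to obtain a plausible
   future map.
3. **Valuation** — attach a monetary value to each date's landscape with the
   equivalent-factor (benefit-transfer) method.
4. **Sensitivity** — relate the change in ecosystem service value (ESV) to
   the amount of land conversion with an elasticity-style index, per
   administrative zone (township).

A seeded synthetic-landscape generator stands in for satellite data so every
stage is testable end to end.

## Models and formulas

### Transition matrix and dynamic degrees

For dates $t_1, t_2$ separated by $T$ years, the transition matrix entry
$A_{ij}$ is the area (km²) that was class $i$ at $t_1$ and class $j$ at
$t_2$. Cells that are nodata at either date are excluded from both, so row
totals equal class areas at $t_1$ and column totals class areas at $t_2$.

The **single land-use dynamic degree** of one class with start area $U_a$
and end area $U_b$ is

$$K = \frac{U_b - U_a}{U_a}\cdot\frac{1}{T}\cdot 100\%$$

per year. A class absent at the start ($U_a = 0$) has an undefined rate and
is flagged rather than reported as infinite. The **comprehensive land-use
dynamic degree** is the annualized share of the landscape that changed
class:

$$R = \frac{\sum_{i \ne j} A_{ij}}{\sum_{i,j} A_{ij}}\cdot\frac{1}{T}\cdot 100\%.$$

Every off-diagonal conversion is counted once and the denominator is the
total analysed area at the period start. Both statistics are computed at
full precision; rounding to two decimals is a reporting choice.

When a published transition table is entered by hand (see
`qinghai_transition_1990_2000()`), its printed marginal totals can disagree
with the sums of its printed cells by a few hundredths of a km², because
both were rounded independently from unpublished full-precision areas.
Change rates quoted against published totals should therefore be computed
from the published marginals (`qinghai_marginals_1990_2000()`), not from
re-summed cells; the package keeps both.

### Map agreement

`cohen_kappa()` computes chance-corrected cell-wise agreement
$\kappa = (p_o - p_e)/(1 - p_e)$ from the confusion matrix of two aligned
maps. It is the standard validation statistic for a simulated map against
an observed one; $\kappa = 1$ iff the maps agree on every analysed cell.

### Markov estimation and projection

`estimate_transition_probs()` row-normalizes the transition matrix:
$P_{ij} = A_{ij} / \sum_j A_{ij}$, with identity rows substituted for
classes absent at the start so $P$ stays row-stochastic. Projection is the
vector-matrix product $a_{t+T} = a_t P$, which conserves total area and, by
construction, reproduces the calibration column totals when applied to the
calibration row totals.

### The CA allocator

The Markov model says how much area each class gains or loses; the cellular
automaton decides where. The published studies this chain follows specify
the ingredients — per-class suitability surfaces taken from the Markov
conditional probabilities, a 5×5 von Neumann neighborhood (the 12 cells
within Manhattan distance 2), annual iterations — but not the allocation
rule itself. The rule implemented here, documented as this package's design:

* Final per-class cell targets are the initial counts projected through
  $P$ and rounded by the largest-remainder method (sums are preserved
  exactly). Interim targets for iteration $k$ of $n$ interpolate linearly
  between initial and final counts.
* Each iteration, a class above its interim target releases its
  lowest-scoring member cells; classes below target claim released cells in
  descending score order. The score of cell $x$ for class $j$ is
  $S_j(x)\,(\varepsilon + f_j(x))$ where $S_j(x) = P[c(x), j]$ is the
  suitability given the cell's current class $c(x)$, $f_j(x)$ is the
  fraction of its (border-truncated) 12-cell neighborhood in class $j$, and
  $\varepsilon > 0$ (default 0.1) lets a growing class nucleate new patches
  away from existing ones.
* Ties are broken by one seeded random permutation fixed per run, so
  results are bit-identical under a fixed seed without spatial bias.

Because released and claimed counts balance exactly every iteration, the
allocator meets its integer targets exactly; the `area_tolerance` argument
(default 0.5% of the landscape) is an internal consistency check, not a
knob. Suitability is looked up from the cell's *current* class each
iteration, so a cell converted early influences its neighbors' scores in
later iterations, which is what produces patch growth rather than salt-and-
pepper change.

Annualization of a decade kernel is by linear interpolation of targets
rather than a matrix root: empirical kernels frequently have no real
stochastic root, and no annual kernel is observable. A matrix-root option
was considered and dropped — it would change nothing the package asserts
while failing unpredictably on valid inputs.

### Equivalent-factor valuation

The unit value of cropland food production is
$$E_a = \frac{1}{7}\,\frac{\sum_i m_i p_i q_i}{M}$$
(Yuan/hm²/a) from crop sowing areas $m_i$ (hm²), prices $p_i$ (Yuan/t) and
yields $q_i$ (t/hm²/a), with $M = \sum_i m_i$; the conventional 1/7 factor
makes one "value unit" a seventh of the mean grain revenue per hectare.
Every service $i$ of ecosystem $j$ is priced as $E_{ij} = e_{ij} E_a$ from
a 9-service × 6-ecosystem table of unitless equivalent factors, and the
landscape value is
$$\mathrm{ESV} = \sum_j A_j \sum_i E_{ij}$$
with areas converted from km² to hm² (×100). The class→ecosystem mapping is
explicit configuration: a 7-class legend maps onto 6 ecosystem columns, and
construction land defaults to zero value (its ecosystem function is treated
as lost), which can be overridden via the mapping. The shipped factor table
(`equivalent_factors_template.csv`) is an illustrative template with the
canonical structure — regional applications should substitute locally
calibrated factors.

### Sensitivity of ESV to land change

$$SI = \left|\frac{\mathrm{ESV}_{t_2} - \mathrm{ESV}_{t_1}}{R}\right|
 \cdot \frac{1}{t_2 - t_1} \cdot 100\%$$

with $R$ the comprehensive dynamic degree of the same period as a
percentage number (1.61, not 0.0161). $SI$ is zero iff ESV did not change
and undefined (NA, flagged) when no land changed. The ESV unit propagates
linearly into $SI$ and published values are not reconcilable with any
single unit convention, so the unit is configuration; the zonal wrapper
defaults to ESV in 10⁹ Yuan. `classify_si_change()` compares per-zone SI
between two periods and reports increase/decrease/tie groups with counts,
areas, and shares; ties form a third category rather than being folded into
either side, and zones with undefined SI are excluded with a logged count.

## The synthetic generator

`generate_landscape()` builds patchy categorical maps by multi-seed region
growing: about `n_cells / patchiness` seeds are planted, classes are
assigned to seeds by largest-remainder allocation of the requested weights
(so expected proportions are exact), and unlabeled cells repeatedly adopt
the label of a random labeled 4-neighbor. `evolve_landscape()` advances a
map one period under a known row-stochastic kernel, optionally biasing each
cell's row toward classes present in its 12-cell neighborhood by
$(1 + c\,f_j)$ re-weighting. With the clustering bias at zero the draw is
exactly i.i.d. from the kernel rows, which is what makes the generating
kernel recoverable by cross-tabulation — the package tests recover it
within an L1 row error of 0.02 on a 512×512 pair for rows occupying at
least 2% of cells.

What the generator emulates: controlled class proportions, spatial
autocorrelation (patches), a known Markov transition structure, and
contiguous zone partitions (`generate_zones()`, Voronoi-like growth). What
it does not: classification error, georeferencing, anisotropy, class-
dependent patch geometry, or any covariate structure (elevation, roads).
Passing tests on synthetic data therefore demonstrate correctness of the
computations and the allocator's contract — not predictive skill on real
landscapes, which the driver-free suitability model inherently limits.

## Numerical choices and degenerate inputs

* All areal math is per-cell; a 30 m cell is 0.0009 km². Geospatial
  referencing beyond cell size is not carried.
* Largest-remainder rounding everywhere fractional areas meet integer
  cells; ties broken by index order.
* Classes absent at a period start yield flagged-undefined rates, never
  infinities; zones with zero change yield flagged-undefined SI.
* Neighborhoods are truncated at map borders and nodata cells are excluded
  from every computation and never modified.
* Kernel rows and class weights are validated to sum to 1 within 1e-9.

## Problem sizes

The test suite exercises proportions, adjacency and kappa-null properties
at 256×256, kernel parameter recovery at 512×512, CA target attainment at
256×256 with 10 annual iterations, and the full pipeline on a 48×48
three-date landscape with 6 zones — sizes chosen so the whole suite runs in
well under a minute while keeping the binomial sampling bounds the
assertions rely on.

## Worked example

```{r example}
# published 1990-2000 transition table for a 55,836 km2 region
tm <- qinghai_transition_1990_2000()
round(cludd(tm), 2) # % of the region changing class per year
dynamic_degrees(tm)

# Markov calibration and projection
model <- estimate_transition_probs(tm)
round(project_areas(model, rowSums(tm$areas)), 2)
```

```{r synthetic}
# synthetic end-to-end: generate, evolve, simulate, value
g1 <- generate_landscape(96, 96, rep(1 / 7, 7), patchiness = 20, seed = 1,
                         date_label = "2000")
g2 <- evolve_landscape(g1, estimate_transition_probs(tm)$P,
                       clustering_strength = 0.4, seed = 2)
m <- estimate_transition_probs(crosstab(g1, g2, 10))
sim <- ca_simulate(g1, m, iterations = 10, seed = 3)
cohen_kappa(sim, g2)

factors <- read_factors_csv(system.file("extdata",
  "equivalent_factors_template.csv", package = "luccesv"))
E_a <- food_production_unit_value(generate_crop_economics(seed = 4))
prices <- unit_price_table(E_a, factors)
glance(esv_totals(g2, prices, year_label = "2010"))
```

## Known limitations

* Suitability is history-only (Markov conditional probabilities); no
  covariates, constraint masks, or multi-criteria evaluation.
* No reprojection or resampling — inputs must be co-registered; the raster
  format is single-band integer ESRI ASCII grid.
* Valuation is nominal-Yuan benefit transfer; no biophysical modeling, no
  localization of factors, no discounting.
* The CA allocation rule is this package's explicit design where the
  literature leaves the rule unstated; alternative allocators (e.g.
  all-cell reallocation per iteration) would meet the same area targets
  with different spatial detail.
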