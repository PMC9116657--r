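---
title: "Weight-based analysis of commingled cremation deposits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-based analysis of commingled cremation deposits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cremains)
```

## The problem

A cremation platform used repeatedly over generations leaves a deposit of
minutely fragmented, commingled burnt bone in which almost nothing is
anatomically diagnostic. Element-count MNI estimators bottom out at a
handful of individuals while the deposit may weigh tens of kilograms.
`cremains` treats the **weight record** — grams of bone per excavation
square, stratigraphic unit, size class and gross anatomical region — as
the primary quantitative signal, and organises three analyses around it:
fragmentation/selection indices, spatial density structure, and a
demographic weight budget for the minimum number of individuals.

## Data model

One row of a deposit is one weighed lot: `us` (stratigraphic unit,
10–20), `cut` (optional subdivision `I`–`IV` or the surface label
`roof`), `row` (grid letter), `column` (grid number), `size_class`
(`lt20`, `ge20`, `tooth`), `region` (`cranial`, `postcranial`, `tooth`,
`undetermined`) and `weight_g`. Teeth are a category of their own, not a
subdivision of the size split, because composition is conventionally
reported as three disjoint shares. Duplicate keys are collapsed by
summation; rows are kept in a canonical sort so writes are byte-stable
and `read ∘ write` is the identity.

The default grid is 18 letter rows (A–R) by 28 columns of 0.25 m cells.
Two caveats are deliberate: the letter alphabet is configurable, because
excavation grids sometimes skip letters and the published coding for the
reference site does not enumerate them; and the declared grid (504 cells,
31.5 m²) is larger than that site's stated 416 excavated squares /
26 m². We accept both declarations rather than reconcile them — the grid
is a coordinate frame for addressing, not an area estimate, and no
analysis here depends on empty cells beyond the excavated rectangle.

## Indices

The fragmentation index `w(<20 mm) / w(>20 mm) × 100` and the CPC index
`w(cranial) / w(post-cranial) × 100` are percent-scaled weight ratios. A
zero denominator returns a flagged undefined result instead of an error,
so per-square maps over sparse grids survive squares holding a single
size class.

A regional "average" index is computed by **pooling**: weights are summed
over the member squares before the ratio is taken. Pooling is the
default because it reproduces desk arithmetic done on summed tables
(e.g. shares of 76.6% and 22.5% pool to an index of 340.4, reported as
340); the alternative — the mean of per-square ratios over squares where
the ratio is defined — weights every square equally regardless of its
mass and can differ substantially on skewed deposits. Both are exposed
(`pooled_indices(method = "mean")`, `regional_cpc(method = "mean")`)
since published regional values do not always state which convention was
used.

Internal values are full precision; presentation rounds half away from
zero to one decimal (`round_half_up()`), matching how such indices are
conventionally printed.

## Spatial analysis

`weight_map()` aggregates a (optionally stratum-filtered) deposit onto
the complete grid; its cell sum always equals the filtered total.
`transect()` profiles a row or column; `top_squares()` ranks hotspots
with deterministic lexicographic tie-breaks; `region_stats()` reports
totals, per-square means and metric extent for any member set.

Two detection rules are deliberately loose:

* **Core region.** The default is the smallest axis-aligned rectangle
  containing all cells at ≥ 10% of the map maximum (`detect_core()`),
  but any explicitly supplied member list is honoured — field reports
  usually give the extent of the dense area, not the rule that produced
  it.
* **Peripheral clusters.** `peripheral_clusters()` finds connected
  components of non-zero cells outside the core, with 4- or
  8-connectivity (8 by default, since diagonal adjacency on a 25 cm grid
  is still physical contiguity). Accumulations delineated during
  excavation are, however, often *visual* groupings that are not
  graph-connected; `cluster_stats()` therefore scores an arbitrary
  explicit square set, so printed groupings can be reproduced without
  guessing a detection rule.

## The weight-budget MNI model

Let classes `c = 1..k` have death-structure ratios `r_c` and per-capita
mass contributions `m_c`. The forward model for counts `n·r` is
`W(n) = n Σ_c r_c m_c`; the inverse solver returns
`n* = round(W_obs / Σ_c r_c m_c)` and MNI `n* Σ_c r_c`.

* **Primary deposition:** `m_c` is the full expected mass of a complete
  burnt skeleton. Shipped reference values for a Late Bronze Age Alpine
  population: 2,500 g (adult male), 1,800 g (adult female), 500 g
  (subadult; an alternative 1,000 g adolescent figure can be added as
  its own class).
* **Residual deposit:** `m_c = expected − collected`, the mass left on
  the pyre after urn collection, with reference urn masses 1,695 g
  (adult male) and 1,443 g (adult female).

The default death structure 1:1:2 (male : female : subadult) encodes a
balanced sex ratio and the ~50% subadult mortality of pre-industrial
populations, and is fully configurable. Ratios given as integers are
reduced to smallest terms so the "demographic unit" is well defined.

**Rounding.** The default is nearest-unit, halves up. This is a
deliberate choice over floor: the reference deposit's 63,555 g gives
63,555 / 5,300 = 11.99 units under the primary scenario, which any
sensible reading makes 12 units (MNI 48), and 63,555 / 1,476 = 43.06
under the residual one (43 units, MNI 172). `floor` and `ceil` are
exposed for users who want a strict lower- or upper-bound reading of
"minimum". The solver is validated against an exhaustive-search oracle
and is exact on forward-generated totals.

**The subadult-residual discrepancy.** The published residual budget
prints the subadult term as a subtraction, `500 − 157 g`, yet its own
total (63,468 g at counts 43/43/86) and MNI (172) are arithmetically
consistent only if the subadult per-capita residual *is* 157 g — the
reference subadult urn average used directly. Rather than silently pick
a side, the package ships both scenario variants: `salorno_b` carries an
explicit 157 g residual override (and reproduces the published numbers);
`salorno_b_printed` implements the literal subtraction (343 g). Neither
is declared correct; analyses run both, and the comparison report keeps
them side by side.

`compare_hypotheses()` deliberately computes **no verdict**: the model
gives each hypothesis an MNI and a misfit, but adjudication between
primary and residual deposition is archaeological (element
representation, cranial share, spatial patterning), not a smaller
residual.

A generational capacity model complements the budget:
`generational_deaths(span, generation_length, family_size)` gives
`span / generation_length` generations times the deaths per generation —
e.g. a 200-year use span at 25-year generations and nuclear families of
6 gives 8 generations and 48 deaths, the natural cross-check on a
primary-deposition MNI.

## The synthetic generator

`simulate_deposit()` composes three seeded stages, each independently
reproducible from streams derived from one master seed:

1. **Community** (`simulate_community()`): `generations × family_size`
   deaths. By default class counts are fixed at their expected
   proportions ("expected" assignment) — the demographic structure is an
   assumption of the model, so the generator holds it exactly and lets
   noise enter through masses; fully stochastic per-death assignment is
   available. Masses are normal, truncated at zero, with defaults
   2,500 ± 250, 1,800 ± 250 and 500 ± 125 g: the adult spreads are a
   quarter of the cited modern cremation-weight ranges (2–3 kg and
   1.5–2.5 kg); no range is documented for subadults, so their spread
   keeps the adults' relative width. Setting `sd_g = 0` gives the exact
   textbook community (48 deaths → 63,600 g).
2. **Fragmentation** (`fragment_individual()`): each skeleton's mass is
   split, conserving mass exactly, into tooth (deterministic fraction,
   default 0.008), sub-20-mm and over-20-mm cranial/post-cranial. The
   sub-20-mm fraction is Beta-distributed with mean
   `FI / (FI + 100)` (default FI target 340) and the cranial fraction of
   identifiable mass Beta-distributed around 0.15; concentrations
   default to 50 and `Inf` disables the noise. Pooled indices of large
   simulated deposits converge to these targets.
3. **Scatter** (`deposit_spatially()`): each per-category mass is split
   into `n_lots` equal lots (default 20, so per-square tables resemble
   the many small weighed bags of real recording) and displaced from the
   pyre centre by an isotropic 2-D Gaussian. The scatter sd defaults to
   0.5 m; this is purely an implementation choice — no published
   dispersion parameter exists for such deposits — sized so that most
   mass falls within the central ~2 m while the periphery is non-empty.
   Positions are quantised to cells and clipped to the grid edge. An
   optional collection step removes up to a per-class mass per
   individual before deposition, taking over-20-mm mass first (cranial
   and post-cranial in proportion), then sub-20-mm, then teeth —
   ossilegium favours large identifiable pieces, so residual deposits
   come out more fragmented, as the residual hypothesis expects.

What the generator does **not** emulate: combustion physics and
temperature-dependent shrinkage, post-depositional comminution
(trampling, freeze–thaw, gravel friction), non-isotropic or multi-pyre
scatter, and stratigraphic complexity (everything lands in one unit).
Passing recovery tests therefore shows the pipeline's arithmetic and
statistical behaviour is sound under the model's own assumptions, not
that a real deposit satisfies them.

## Numerical choices and degenerate inputs

* Conservation is enforced and tested at 1e-9 g across aggregations and
  1e-6 g through the simulation pipeline.
* Undefined ratios (zero denominators) are flagged, never thrown.
* Hotspot ties break lexicographically (row letter, then column);
  repeated runs and writes are byte-identical; reports carry no
  timestamps.
* An empty deposit has total 0, an empty map an undefined centroid
  (error), and an empty selection sums to 0.
* Problem sizes in the shipped tests are small by design: communities of
  10–200 individuals, 50-replicate recovery sweeps, 1,000-instance
  solver/oracle comparisons — the whole suite is desk-scale arithmetic
  on a 504-cell grid.

## Limitations

The weight budget is deterministic arithmetic: it propagates no
uncertainty in class masses or death structure (a sensitivity sweep over
those inputs is straightforward with `purrr` over
`demographic_scenario()`s, but no probabilistic demography is built in).
Spatial analysis is 2-D per stratum; cuts are filters, not volumes. And
an MNI from a weight budget is conditional on its reference masses:
changing the regional reference population changes the answer, which is
exactly why scenarios are explicit, serialisable objects.
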