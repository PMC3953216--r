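---
title: "Modelling ecosystem-service flows with spanflow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ecosystem-service flows with spanflow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanflow)
```

## The conceptual model

`spanflow` quantifies ecosystem services from the beneficiary's side. Instead
of mapping only the *potential* of ecosystems to supply a service, it
simulates the movement of a *service carrier* — water, sediment, CO2, visual
information — from **source** regions, past **sink** regions that absorb it,
to the **use** regions where beneficiaries live. The amount of carrier that
actually reaches people (or, for hazards, is kept away from them) is the
basis of value, and it can differ dramatically from the in-situ supply.

Two semantic axes classify every benefit:

* **provisioning vs preventive** — carrier contact benefits users (drinking
  water, scenic views) vs harms them (flood water, sediment), in which case
  sinks provide the benefit by mitigation;
* **rival vs non-rival** — use depletes the carrier for other users (water
  withdrawal) vs not (a view enjoyed by many).

A simulation is run twice: a *possible* pass with every sink capacity forced
to zero, and an *actual* pass with sinks active. Together with the
theoretical (pre-flow) layers this yields the full output taxonomy:

| group | maps | meaning |
|---|---|---|
| theoretical | source, sink, use | in-situ supply, absorption capacity, demand, ignoring flow |
| possible | source, use, flow | what flow paths could deliver if no sink intervened |
| actual | source, sink, use, flow | delivery with sinks active |
| inaccessible | source, sink, use | supply/demand unservable for lack of flow connections |
| blocked | source, use, flow | flow stopped by sinks (possible − actual) |

The subtraction identities (`blocked = possible − actual`,
`inaccessible_source/use = theoretical − possible`, `inaccessible_sink =
theoretical − actual`) are enforced by `derive_output_maps()` to 1e-9 and
verified independently in the test suite.

## Routers

The diversity of carriers reduces to four transport modes
(`router_spec()`):

* **`d8_downslope`** — hydrologic carriers. Each cell drains to its steepest
  strictly-lower 8-neighbour (drop/distance, diagonal distance
  `cell_size * sqrt(2)`); pits and flats are terminal. One sweep in
  topological (upstream-to-downstream) order moves all carrier to
  quiescence; the model is intentionally not temporally referenced, so there
  are no time steps. Within a cell, sinks act on the carrier before
  beneficiaries — sinks are interposed on the flow path. Rival users
  withdraw `min(remainder, unmet demand)`; non-rival users register contact
  without depletion.
* **`line_of_sight`** — informational carriers (scenic quality), non-rival
  only. Each source within `max_distance` of a user contributes its value if
  the straight cell-center ray clears the terrain; sinks on the ray are
  additive attenuators with a floor at zero. Whether attenuation should be
  additive or multiplicative is genuinely open; additive was chosen because
  sink values are expressed in the same ranked units as sources, and the
  choice is flagged for revisit.
* **`access_cost`** — beneficiaries travel to sources (open space,
  fisheries) over a cost surface, reaching anything within `max_cost` by
  8-connected least-cost distance (step cost = mean of endpoint costs times
  the distance factor). Rival sources are allocated in increasing cost
  order, splitting equal-cost claims proportionally to unmet demand;
  non-rival sources serve every reaching user. Sinks along the least-cost
  path attenuate what is delivered.
* **`global_mix`** — well-mixed carriers (CO2). The pool
  `sum(source) − min(sum(source), sum(sink))` is allocated proportionally to
  demand, capped by demand; flow maps are uniform pool density.

### Numerical conventions worth knowing

* **Conservation.** For rival `d8` problems the exact mass balance is
  `sum(actual_use) + sum(actual_sink) + terminal outflow =
  sum(theoretical_source)`; carrier leaving the grid at terminal cells is
  reported separately (`terminal_outflow`) and counted as neither delivered
  nor blocked.
* **Attribution.** `actual_source` credits delivered benefit back to
  originating cells. Shares are computed from the *sink-free* (possible)
  pass and then scaled by the actual deliveries. This deliberate choice
  keeps every taxonomy map nonnegative: if shares were recomputed under
  sinks, a sink on one tributary would shift use-credit toward the other
  tributary and `blocked_source` could locally go negative. The same
  convention fixes each non-rival user's demand-rationing factor in the
  sink-free pass. For non-rival benefits a source is credited with the
  largest contact any single user makes with its carrier, so credit never
  exceeds the source value even though total non-rival use may (deliveries
  multiply across users; total flow can exceed the source total).
* **Determinism.** Equal-cost and equal-score ties break by fixed rules
  (clockwise-from-East neighbour order, cost order then cell index,
  candidate id); rerunning any simulation is bit-identical.
* **Visibility.** The terrain profile between two cell centers is the
  bilinear interpolation of cell-center elevations, evaluated at 100 uniform
  stations per ray; stations within half a cell of an endpoint belong to the
  endpoint cell. A cell is visible when no station rises above the sight
  line (strict, tolerance 1e-9). The observer is always visible.

## Probabilistic production functions

Source, sink and use surfaces are often uncertain. `bn_engine` supplies
discrete Bayesian networks as production functions: `apply_bn()` discretizes
evidence layers per cell (bin edges map continuous drivers to node states;
out-of-range values clamp to the edge bins), treats missing evidence as
*marginalized, not imputed* — a cell with no evidence simply receives the
prior, with correspondingly wider uncertainty — and attaches the exact
posterior (`infer_posterior()`, factor-product variable elimination) of the
target node to each cell.

`summarize_distribution()` renders any distribution layer as the paired
value/uncertainty maps used throughout: expected value with the coefficient
of variation for numeric nodes (CV is 0 for a certain zero and nodata for a
zero mean with positive variance), modal class with the Shannon diversity
`−sum(p ln p)` for categorical ones. The natural logarithm is used; ties in
the mode break to the lowest state index. Nodes without numeric midpoints
are categorical by definition.

Training (`train_cpts()`) uses Dirichlet-style additive smoothing,
`(count + alpha) / (config count + alpha * k)`, default `alpha = 1`;
`alpha = 0` gives maximum-likelihood frequencies, with unseen parent
configurations set uniform under a warning. Network *structure* is always
user-supplied: structure learning is out of scope, and no accounting is
attempted for structural uncertainty.

## Hybrid erosion production function

`hybrid_erosion()` demonstrates spatially partitioned model assembly: on
gentle slopes annual soil loss is the deterministic RUSLE product
`A = R K LS C P`; where slope exceeds 20 % — beyond the empirical support of
RUSLE — a Bayesian network over soil, precipitation and vegetation classes
takes over. The threshold comparison is strict (`> 20`), so boundary cells
are RUSLE. Both regimes live in one distribution layer: RUSLE cells carry a
point mass, steep cells a posterior. The shipped `example_erosion_bn()` is
an illustrative synthetic net (its CPTs derive from a simple additive risk
score) intended to be replaced by a locally calibrated model; it represents
no real region. RUSLE factor derivation from primary data is likewise out
of scope — the factors are inputs.

`sediment_concentration()` converts delivered sediment and water totals to
kg/m3.year, the comparative contamination indicator used to contrast
regions; such figures are semi-quantitative comparisons, not physical
predictions.

## Monte-Carlo uncertainty propagation

`propagate()` carries input uncertainty through the flow model: each draw
samples every uncertain cell independently at a state midpoint, runs the
full SPAN simulation, and per-cell means and CVs are accumulated for every
requested output. Because the taxonomy identities hold for each draw, they
hold for the means by linearity. Seeding is explicit: one master seed, with
per-draw streams derived as `(seed * 1000003 + draw) mod (2^31 − 1)` so any
draw can be reproduced individually. Cells are sampled independently —
there is no spatial copula — which is a known limitation: spatially
correlated input errors will widen output uncertainty beyond what these CV
maps show. Analytic variance propagation is provided only for the
well-mixed router (`propagate_global_mix_analytic()`), whose outputs are
linear in the inputs away from the caps; elsewhere Monte Carlo is
authoritative.

## Model assembly

`assembler` re-implements context-driven model resolution at desk scale.
Candidates (datasets or models) carry metadata; `score_candidate()` ranks
them by a weighted sum of six criteria, each normalized to [0, 100]:
semantic specificity (matching tag-path depth over target depth), scale
specificity (context coverage), detail (context cell size over candidate
resolution, capped at 1), semantic distance (same ontology tag 100, else
50 — no finer metric is defined, so a binary convention is declared),
currency (time-period coverage), and the user-attributed rank (50 when
unspecified). Weights default to uniform and are configuration, not code.
Ordered tag paths stand in for ontology reasoning; genuine OWL semantics
are out of scope.

`resolve()` builds the model tree: guard predicates over context variables
filter candidates, and predicates that evaluate to spatial masks let
several candidates serve one concept in disjoint segments — exactly how the
RUSLE/steep-slope pair partitions a landscape by the 20 % slope line. Model
candidates recurse into their requirements; cycles are errors; every choice
is recorded with its score breakdown as a provenance record, and resolution
is a pure function of (concept, registry, context). Scenario overrides
(`apply_scenario()`) insert replacement candidates with overriding
priority, so everything downstream of the overridden concept re-resolves
while the baseline registry is untouched.

`compare_scenarios()` reports scenario effects the way practitioners read
them: per output map, the percent change of the map *total* against
baseline, one decimal, rounded half away from zero. Totals rather than
cellwise means were chosen; a consequence is that the figures are not
invariant to changes in the nodata footprint, which is documented here
rather than hidden. Zero-baseline rows print as `n/a`, never as infinity.

## Synthetic landscapes and what the tests show

All tests run on synthetic data from `synth_landscape`: a seeded Gaussian
field smoothed by iterated 3x3 neighbourhood averaging (chosen over
spectral synthesis for dependency-free, cross-platform reproducibility) and
rescaled to the requested relief; clumped land cover by seeded region
growing with an expected patch size in cells; per-class source/sink/use
intensities with closed-form layer totals. Defaults describe a plausible
temperate mosaic: 20 x 20 cells of 30 map units, 50-unit relief, three
cover classes of mean patch size 15 with forest as the main source and
settlement as the main demand center.

The generator emulates the *statistical* structure real inputs would have —
spatial autocorrelation, patchiness, class-linked intensities — but not any
real region's hydrography, seasonality, or measurement error. Passing
tests therefore demonstrate algorithmic correctness (oracle equivalence,
conservation, identity enforcement, parameter recovery, reproducibility),
not predictive skill on real landscapes; published regional figures
reproduced in the examples (sustainability ratios, the sediment contrast)
are recomputed from their printed inputs, since the underlying regional
datasets are not redistributable.

Problem sizes used throughout the suite — 5 x 5 to 8 x 8 grids, networks of
up to 6 nodes, 2000-draw Monte Carlo — were chosen so that every oracle
(joint enumeration, per-trajectory path walking, dense ray sampling,
relaxation shortest paths) stays exhaustively checkable; all of the
algorithms are O(cells) to O(cells^2) and scale routinely to practical
raster sizes.

## Known limitations

* Single-successor D8 routing: no multiple-flow-direction dispersion,
  infrastructure re-routing, or vector hydrography.
* Non-rival line-of-sight sink attenuation is additive by declaration.
* Independent-cell sampling in Monte Carlo (no spatial correlation of
  uncertainty).
* The assembler's semantic criteria use declared normalizations; the
  ranking literature it mirrors names the criteria but not their numeric
  forms.
* No reprojection: all layers must share one grid; `align()` only resamples
  within a common coordinate system.
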