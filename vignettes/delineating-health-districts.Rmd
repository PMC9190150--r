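---
title: "Delineating natural catchment health districts from birth-admission flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating natural catchment health districts from birth-admission flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nchdzone)
```

## The problem

Health planners need areal units whose population actually uses the
facilities inside them. Administrative districts rarely have this
property: hospitals concentrate in towns, many districts contain none,
and women routinely cross district borders to give birth. Indicators such
as "CEmONC hospitals per 100,000" computed on such borders mix a
facility's numerator with somebody else's denominator. A *natural
catchment health district* (NCHD) is instead delineated from observed
origin–destination flows so that, by construction, a high share of
journeys start and end inside the same zone.

`nchdzone` implements the full pipeline: flow ingest and aggregation,
the hospital-anchored seeding, the iterative merge loop driven by
self-containment and connectance, automated contiguity repair, a
scale-matched baseline, per-zone access indicators, and a synthetic-data
generator that stands in for the restricted routine registers such
analyses normally run on.

## The procedure and its assumptions

The unit of analysis is the health sub-district; the input is a table of
flows (origin sub-district, destination hospital, count of women). The
procedure assumes flows are complete enough to reflect revealed
preference, and that a partition of sub-districts (no splitting below
that level) is an acceptable zone geometry.

1. **Pre-processing.** Community-level records are summed to
   sub-districts (`aggregate_to_units()`), conserving totals exactly.
   Sub-districts with no located facility and no recorded outgoing flow
   are unioned into a same-district neighbour
   (`merge_birthless_units()`): such units carry no evidence about
   catchment membership, and leaving them out would break the partition.
   The receiving unit is the same-district rook neighbour with the
   longest shared boundary (nearest same-district centroid if there is no
   such neighbour) — "nearby" made deterministic.
2. **Seeding.** Every hospital seeds a candidate zone; each unit joins
   the zone of the hospital receiving the plurality of its flows. Ties go
   to the smallest facility identifier. Assignment is *membership only*:
   the flow records are never rewritten. This is the main interpretive
   fork in the procedure — reassigning the flows themselves would make
   every seed zone perfectly self-contained and the merge loop vacuous —
   so the package assigns membership and keeps the observed cross-zone
   flows visible to the loop. A hospital whose own unit plurality-chose a
   different hospital does not seed a zone; it co-anchors the zone its
   unit joined.
3. **The loop.** Repeatedly: compute demand- and supply-side
   self-containment for every zone; take the zone minimising the smaller
   of the two as the merge candidate; compute its connectance to every
   other zone; merge it into the argmax. Stop when every zone's minimum
   self-containment reaches the threshold, or one zone remains. Zones
   are only merged, never dissolved, so the loop performs at most
   (initial zones − 1) merges and the global internal-flow share is
   non-decreasing along the trace (merging i into j moves `T[i, j]` and
   `T[j, i]` onto the diagonal).
4. **Contiguity repair.** Flow-led merging can strand spatial fragments
   (a sub-district whose women mostly travel to a distant hospital). For
   each zone the connected components of its members are found under the
   configured adjacency; the component holding the anchor hospitals is
   kept (largest component if anchors are split or absent, ties to the
   component with the smallest unit id) and every other fragment is
   reassigned wholesale to the adjacent zone with the longest total
   shared boundary, iterating until all zones are connected. The original
   procedure did this step by hand; the package automates it with
   "highest contiguity" read as longest shared boundary. Repair can
   perturb self-containment, and the package deliberately does **not**
   re-enter the merge loop afterwards: both the pre- and post-repair
   self-containment tables are reported (`tidy()` returns both stages),
   so the cost of spatial cleanliness is visible rather than hidden.

### The baseline

`comparable_zones()` is the control: assign flows by plurality exactly as
above, then repeatedly merge the zone with the smallest *supply-side*
self-containment into its rook-contiguous neighbour with the smallest
supply-side self-containment, down to a target count (by default the
count the main delineation produced). Because it merges only along
adjacency it needs no repair. Comparing the two at equal zone counts
isolates the contribution of connectance-guided merging: aggregation
alone raises self-containment mechanically, so the fair question is
whether flow-guided zones beat equally coarse flow-blind ones. When a
candidate zone has no contiguous neighbour (possible only when plurality
seeding created a spatially fragmented seed zone), the baseline falls
back to the least self-contained zone overall; seeds and enclaves are not
otherwise special-cased.

## Numerical conventions

* Self-containment of a zone with zero row (or column) sum is defined as
  1: a zone generating (receiving) no trips is vacuously self-contained.
* Any connectance term with a zero denominator contributes 0. The index
  is then always finite, symmetric, and in `[0, 2]`.
* Every argmin/argmax tie in the pipeline breaks to the smallest
  identifier (radix/C-locale order), making the whole delineation
  deterministic for fixed inputs.
* If the merge candidate exchanges no flow with any zone (connectance
  identically 0 — an isolated zone), the partner falls back to the
  spatially adjacent zone with the longest shared boundary. A genuinely
  isolated *and* self-contained zone never reaches this code path: it
  simply never becomes the merge candidate, which is the behaviour such
  zones should have.
* Flow counts are integers throughout; totals are conserved exactly at
  every step (asserted in the tests).
* Percentages in completeness reports are rounded half-up to one decimal,
  matching routine reporting style.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.96 | Minimum per-zone min(demand, supply) self-containment. High because seed zones are already fairly self-contained and planners want minimal cross-border use. |
| `contiguity` | `"rook"` | Shared-edge adjacency; `"queen"` additionally accepts corner contact. |
| `target_count` (baseline) | main delineation's count | Matched-scale comparison. |
| `denominator` (indicators) | `"population"` | `"pregnancies"` rescales by an expected-pregnancy rate, for rates per pregnancy rather than per resident. |

WHO benchmark flags are inclusive (a zone with exactly 22.8 midwives per
10,000 meets the 22.8 benchmark).

## What the synthetic generator emulates — and what it does not

The generator (`simulate_scenario()`) produces worlds with the
statistical signatures of a routine birth register in a setting like
Ghana's Eastern Region:

* ~250 sub-district units on a lattice, grouped into 33 contiguous,
  balanced districts; ~4 communities per unit (≈1,000 communities).
* Births per community drawn from a lognormal with median ≈7 and mean
  below 30 (`meanlog = log 7`, `sdlog = 1.7`) — the right-skew of real
  registers, where a few towns contribute hundreds of births.
* 27 hospitals placed in ~11 well-separated towns (farthest-point
  sampling), several hospitals per town. This clustered layout is what
  makes the initial hospital-anchored zones imperfectly self-contained
  (women split between a town's hospitals) while keeping towns well
  separated — the structure that makes merging meaningful. With it, the
  default world's initial internal-flow share lands around 0.65–0.78,
  matching the ~70% seen in real registers. A `"scattered"` layout (one
  hospital per random district) is available for comparison.
* Destination choice by a Huff rule: probability ∝ attractiveness ×
  distance^−β, drawn multinomially per community. The default β = 6 was
  chosen, once, so that the initial self-containment of the seeded zones
  matches the observed ~70% under a purely distance-based rule; weaker
  decay (the textbook β ≈ 1.5–2) spreads births over many hospitals and
  yields initial self-containment near 30%, which no observed register
  resembles — real choice is concentrated by roads, referral habit and
  familiarity, which a single distance exponent must absorb.
* Bypass streams: a small share of communities (default 3%) send most of
  their births (default 80%) to one distant high-attractiveness hospital
  near the region's edge — the long-range streams that produce enclave
  zones and give contiguity repair something to do.
* A gridded population surface (lognormal cell counts) and a facility
  assessment table (sector, midwife counts, nine signal functions with a
  configurable CEmONC-ready fraction, default 0.6).

The generator does **not** emulate: road networks or travel times, water
barriers (the archetypal lake-isolated zone), inter-regional in-flows
from outside the study area, facility closures or reporting gaps, or
seasonal structure. Two consequences matter for interpreting test
results. First, because a single-exponent distance decay produces smooth
catchment boundaries — near-equidistant communities always split between
towns — the 96% criterion usually merges the default gravity world into
one or two zones rather than the ~11 a real region yields; sharp
catchment edges in real data come from barriers and referral behaviour
the generator deliberately omits. The planted-partition mode supplies the
cluster-structured worlds on which exact recovery can be, and is,
demanded (Adjusted Rand Index = 1 at within-zone probability 0.99 across
seeded replicates). Second, passing tests on these worlds demonstrates
algorithmic correctness (every iteration matches brute-force evaluation
of the definitions; every output zone meets the threshold), not that any
particular real region will produce a given number of zones.

## Problem sizes used by the test-suite

The unit and property tests run on 3×3 to 5×10 lattices where brute-force
oracles (exhaustive enumeration of merge steps, double-loop tabulation,
ray-casting point-in-polygon) are cheap; the oracle-equivalence suite
sweeps 100 random flow matrices of up to 8 zones; recovery and
scale-effect properties use 20 seeded replicates of 80–100-unit worlds;
and the stopping-rule guarantee runs on the full 250-unit default world.
These sizes were chosen so the whole suite completes in a couple of
minutes while still exercising every code path at full strength.

## Known limitations

* Geometry is handled natively (vertex-matched tessellations, shared-edge
  adjacency, shoelace areas, cell-centre zonal statistics). Input
  polygons must form a proper tessellation with matched vertices along
  shared boundaries; arbitrary sliver-ridden GIS layers should be cleaned
  upstream. Supported formats are GeoJSON (planar CRS required) and
  gridded CSV for population.
* Zonal population uses the cell-centre rule, not areal weighting; at
  100 m cells the difference is negligible, at coarse cells it is not.
* Zone GeoJSON output groups member-unit polygons as a MultiPolygon
  rather than dissolving them into one outer ring.
* The baseline's tie and enclave handling, the repair rule, and the
  zero-denominator conventions are this package's choices where the
  procedure's published description is silent; all are deterministic and
  documented above.

## A worked run

```{r example, eval = FALSE}
cfg <- scenario_config(n_units = 100, n_districts = 10, n_hospitals = 9,
                       planted = list(k = 3, within_prob = 0.97), seed = 7)
scenario <- simulate_scenario(cfg)
nchd <- delineate(scenario$unit_flows, scenario$geo, scenario$facilities)
glance(nchd)          # 3 zones, internal share 0.971
tidy(nchd)            # per-zone SC, before and after repair
autoplot(nchd)        # zone map
plot_merge_trace(nchd)

base <- comparable_zones(scenario$unit_flows, scenario$geo,
                         scenario$facilities,
                         target_count = glance(nchd)$n_zones)
glance(base)$internal_share   # what flow-blind merging achieves

pop <- zonal_population(scenario$population, nchd$zones, scenario$geo)
compute_indicators(nchd$zones, scenario$facilities, pop)
```
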