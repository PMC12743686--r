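---
title: "Trauma network design under demand uncertainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trauma network design under demand uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumanet)
```

## The problem

A trauma system is judged by whether an injured person reaches definitive
care within a time standard $S$ — conventionally the 60-minute "golden
hour". A region holds demand nodes $i \in I$ (zip-code population
centroids), candidate hospital sites $j \in J$ that could be designated as
trauma care centers (TCCs), and candidate aeromedical depot sites
$k \in K$. TCCs come in two types: $\ell = 1$ treats severe injuries
(Level I/II) and $\ell = 2$ handles non-severe cases (Level III and below).
Daily demand $a_{i\ell}^\omega$ is uncertain; scenario $\omega \in \Omega$
with probability $p_\omega$ represents one realization — for example
historical-year demand or a pandemic-inflated load.

A node is covered by ground if some sited TCC of the required type
satisfies $t^G_{ij} \le S$. Severe demand can also be covered by air: a
helicopter flies from depot $k$ to the scene and on to a type-1 center,
feasible when $t^A_{ki} + t^A_{ij} + t^{load} \le S$ with a 5-minute
patient loading time. These inequalities (all inclusive at the boundary)
define the eligibility sets $N_i$ (ground sites per node), $M_i$ (air
(site, depot) pairs per node), $Q_j$ (nodes per site, the dual of $N$),
and $O_k$ (nodes air-reachable via a depot). The written definition of
$O_k$ does not say which site closes the air triangle; we adopt the
existential reading — $i \in O_k$ iff *some* admissible $j$ exists —
because $O_k$ is used only to accumulate the severe caseload a depot might
carry, and the existential set is the largest demand pool consistent with
the air-coverage condition.

## The two-stage program and its deterministic equivalent

First-stage binaries place facilities before demand is known:
$x^{TC}_{j\ell}$ (a type-$\ell$ TCC at $j$), $x^{AD}_{k\ell}$ (a depot at
$k$), and $z_{kj\ell}$ (both ends of an air pair open). Second-stage
binaries $y^\omega_{i\ell}$, $v^\omega_{i\ell}$, $u^\omega_{i\ell}$ record
per scenario whether demand is covered at all, by ground, or by air. The
objective maximizes expected covered demand,

$$\max \; \sum_{\omega \in \Omega} p_\omega
  \sum_{i \in I} \sum_{\ell \in L} a^\omega_{i\ell} \, y^\omega_{i\ell},$$

subject to: a budget $p^{TC}$ on sited TCCs and $p^{AD}$ on depots with at
most one type per node; linking $z_{kj\ell} \le x^{TC}_{j\ell}$,
$z_{kj\ell} \le x^{AD}_{k\ell}$; coverage logic
$y \le v + u$, $v^\omega_{i\ell} \le \sum_{j \in N_i} x^{TC}_{j\ell}$,
$u^\omega_{i1} \le \sum_{(j,k) \in M_i} z_{kj1}$; per-type caps
$\sum_j x^{TC}_{j\ell} \le r_\ell$; and volume windows per scenario — the
demand reachable from a sited center must lie in
$[V^{min}_\ell, V^{max}_\ell]$, and the severe demand air-reachable via a
sited depot must not exceed $V^{max}_{AD}$. Because the scenario set is
finite, replicating the second-stage variables and constraints per
scenario yields a single mixed-integer program (the deterministic
equivalent), which `build_deterministic_equivalent()` constructs with
every row tagged by its constraint family.

Three published families needed an interpretation, resolved as follows:

* **Minimum volume.** Written unconditionally,
  $\sum_{i \in Q_j} a^\omega_{i\ell} x^{TC}_{j\ell} \ge V^{min}_\ell$ for
  *all* candidates $j$ is infeasible the moment any candidate is left
  unsited (the left side is 0). We implement the conditional form
  $\ge V^{min}_\ell \, x^{TC}_{j\ell}$, which binds only where a facility
  is sited and stays linear because $x$ is binary. The unconditional form
  is retained behind `volume_min_form = "printed"` as a diagnostic: the
  solver and the brute-force oracle both report it infeasible, which is
  the demonstration of why the conditional form is the default.
* **Air cover for non-severe demand.** The air-coverage constraint is
  quantified only for $\ell = 1$; left free, $u^\omega_{i2}$ would be
  unbounded by any placement. It is fixed to 0: air transport is modelled
  for severe patients only, consistent with the depot cap applying to
  severe cases.
* **Pair indicators.** Only the two upper-bound links are printed; since
  $z$ appears solely where it helps coverage, the optimizer sets it freely
  and the reported pairs are post-processed as the product of the parent
  binaries, which is the unique value consistent with both links at the
  optimum.

Volume windows are enforced for every scenario (robustly), exactly as
printed. Note they count *all* demand reachable from a site, so
overlapping facilities double-count shared demand; we implement the
printed form and do not attempt to infer an assignment-based variant the
text does not state.

## Network-design variants

* **BM (benchmark)** fixes the existing designations
  ($\hat J_1$, $\hat J_2$, $\hat K$) at 1 and assesses that network. The
  budgets stay at $p^{TC}$/$p^{AD}$: with the study defaults the fixed
  network consumes them entirely, so BM is pure assessment. By default the
  volume windows also apply to fixed facilities
  (`enforce_volume_on_fixed`); if the existing network violates them, the
  model is reported infeasible rather than silently repaired, and the flag
  exempts fixed facilities when a user wants the assessment anyway.
* **CM (construction)** designs from an empty system and removes the
  per-type cap family entirely. The published variant table cites the cap
  constraint with a garbled label; the per-type cap is the only constraint
  matching its description ("limits the number of TCCs per type"), so that
  is what is removed.
* **IM (improvement)** keeps the BM fixings and relaxes the budgets to
  $p^{TC}{+}\alpha^{TC}$, $p^{AD}{+}\alpha^{AD}$, $r_\ell + \mu_\ell$.
  With $\alpha = \mu = 0$ its feasible set is exactly BM's, which the test
  suite asserts as equality of optima.

## Exact solution

No MILP solver is bundled; instead the package authors an exact
structure-exploiting branch-and-bound (`solve_model()`). The key
observation is second-stage separability: for a fixed first stage the
optimal $y$ is exactly the closed-form coverage indicator, and every
volume row involves a single first-stage binary, so feasibility decomposes
into per-facility admissibility plus budgets and caps. Solving the MILP is
therefore equivalent to maximizing expected covered demand over feasible
site/depot assignments, which the solver does by depth-first search with:

* an incumbent from an incremental greedy heuristic,
* an admissible bound — the weight of node-types already covered or still
  coverable by any remaining placement, respecting exhausted budgets but
  relaxing per-type caps (a valid relaxation), and
* exact leaf evaluation, including any constraint rows it did not
  recognize structurally.

The solver deliberately reconstructs all structure (eligibility sets,
weights, budgets, admissibility) from the model's tagged constraint rows
and objective coefficients, never from the raw inputs. A builder defect
therefore changes what the solver optimizes, and the disagreement with the
independent brute-force oracle — which enumerates placements directly from
the region, scenario and configuration objects with its own variant logic
— is how such defects surface. The test suite requires *exact* objective
agreement between the two routes on randomized instances for all three
variants. When demand is integral and scenario probabilities have at most
three decimals (true of all published instance vectors), both routes
compute the objective as an integer numerator scaled by 1000 and divide
once, so equality is exact in floating point, with no tolerance to hide
behind. Ties among optimal placements are not broken: optima are compared
by objective value only, since placement degeneracy is search-order
dependent.

The search is deterministic; `solve_model()` accepts a seed argument only
so callers can treat backends uniformly. A `time_limit` turns the exact
search into an anytime method that reports `"time-limit"` with the
incumbent; `gap_tolerance` (default 0) allows early pruning at a relative
gap for large exploratory runs — the suite always runs at 0.

## Travel times and geometry

Published studies compute road travel times with commercial GIS tooling.
This package uses a geometric model — great-circle distance for
longitude/latitude input, Euclidean for planar kilometres — with a
circuity multiplier (default 1.4, a standard road-network detour factor)
over a default 45 mph ground speed, and straight-line flight at 120 mph
plus 5 minutes of loading. These defaults are deliberately ordinary
values for mixed rural networks; every analysis function accepts explicit
travel-time matrices (`read_travel_times()`), which bypass the geometry
entirely and are the recommended path when real road times exist.

## Scenarios

`make_instance_probabilities()` returns the four published instance
vectors over scenarios (three historical-demand scenarios plus one
pandemic scenario at weight 0%, 50%, 25% or 75%). Three of the printed
vectors sum to 0.99, 0.98 and 0.999 — rounding in the source — and they
are returned exactly as printed by default, because reproducing published
numbers takes precedence over tidiness; `renormalize = TRUE` rescales
proportionally to an exact unit sum, and `scenario_set()` accepts sums in
$[0.95, 1.05]$ for the same reason. The synthetic sampler
(`generate_demand_scenarios()`) draws independent Poisson daily counts per
node and type — daily incident counts are counts — splitting each node's
mean 20/80 between severe and non-severe demand since the source data's
split is not public, and inflates one designated pandemic scenario by a
multiplier (default 1.5, chosen once as a moderate surge). Real-valued
forecast demand is accepted on input unchanged.

## The synthetic region and what passing tests mean

`generate_region()` emulates the *structure* of the studied service area:
22 counties tiling a 300 km extent, 176 nodes, 86 candidate sites, a
2 + 22 split of existing designations, 7 existing depots co-located with
hospitals, most counties rural and sparse, a single dense hub county
holding both high-level centers. County geometry is an abstract
rectangular tiling — only labels and densities enter the model — and
every county receives at least one node, as a zip-code map would.
`generate_planted_instance()` builds instances whose optimum is known by
construction: well-separated clusters, two co-located candidate sites per
cluster, slack volume bounds, budgets matching the plant, so full
coverage is attainable and the optimal objective equals the total
expected demand.

What these generators do *not* emulate: real road networks (travel times
are geometric), spatially correlated or seasonal demand (scenarios are
independent Poisson draws), population rasters, or facility capacity
attributes (beds, staff). Passing tests therefore certify the
optimization machinery — model construction, variant logic, exact
solving, reporting — on instances with realistic structure; they do not
certify that any particular real region's published coverage numbers are
reproduced, which would require the underlying non-public incident data.

## Numerical choices and degenerate inputs

All times are minutes, speeds mph, distances statute miles internally;
converters sit at the I/O edges. Coverage thresholds are inclusive.
Infinite volume maxima disable those rows' effect without removing the
tagged family. Zero-demand counties report 100% coverage with an explicit
flag (there is nothing to cover); empty node sets yield a valid empty
report; zero budgets or zero demand yield objective 0 with status
`"optimal"`. Feasibility comparisons use an absolute slack of $10^{-9}$;
objective agreement in the dual-route tests is exact, as described above.

## Problem sizes used by the tests

The suite runs the dual-route comparison on 50 randomized instances
(up to 8 nodes, 5 sites, 2 depots, 3 scenarios, integer demand) per
variant, variant-nesting checks on 20+ instances, monotonicity in $S$
over a four-point grid on 10 instances, and planted recovery at 40 and at
176 nodes with 86 candidate sites — the full scale of the emulated
region. These sizes keep the brute-force oracle exact and the whole suite
fast while exercising every code path; the planted large instance shows
the solver at study scale.

## Limitations

The exact search is designed for the study's regime — tight budgets or
planted structure. Adversarial mid-size instances with weak bounds (many
interchangeable sites, loose budgets, no dominant placements) can force
deep enumeration; the `time_limit` argument is the pressure valve.
Chance-constrained or multi-stage extensions, mistriage modelling and
facility capacity attributes are out of scope.
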