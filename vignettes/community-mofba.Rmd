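---
title: "Multi-objective constraint-based analysis of microbial communities"
author: "MOFBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective constraint-based analysis of microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MOFBA)
```

## The modeling problem

A constraint-based model (CBM) of one organism consists of a stoichiometric
matrix $S$ (metabolites $\times$ reactions, reactants negative, products
positive), the steady-state mass balance $Sv = 0$, and flux bounds
$l \le v \le u$ in mmol·gDW$^{-1}$·h$^{-1}$. Flux balance analysis (FBA)
maximizes a linear growth objective $c^\top v$ over this polytope; flux
variability analysis (FVA) then reports, per reaction, the flux range
compatible with retaining a fraction $\alpha$ of the optimum.

A community of $k$ organisms cannot be treated as one bag of reactions:
merging compartments lets one organism's biomass reaction consume another
organism's intermediates, which changes FBA and FVA results (the test suite
keeps a regression model demonstrating this). MOFBA therefore builds a
compartmentalized matrix $S^\sigma$: strain matrices in diagonal blocks, one
*pool* row per shared external metabolite that mirrors each strain's exchange
column with flipped sign, and one pool-to-environment exchange column per
pool metabolite. Steady state applies to pool rows too, so every cross-fed
metabolite is routed through the pool and the environment caps live on the
pool-to-environment exchanges. Sign convention: exchange flux is positive
when the compartment exports to its surroundings, so an environment uptake
cap of $u$ appears as lower bound $-u$ on the pool exchange.

Ratio constraints (for example pinning an oxygenase flux to 3% of a
carboxylase flux) are stored symbolically as linear couplings and appended as
extra LP rows, leaving $S^\sigma$ purely chemical. Couplings may also address
pool exchanges, which is how the fixture expresses community-level nutrient
budgets (e.g. a cap on the *net* nitrogen drawn from the environment across
both nitrate and ammonia).

## MO-FBA: the exact Pareto front

With one objective per member the community problem is a multi-objective
linear program; its solution is the set of efficient flux vectors, whose
image in objective space is the Pareto front. `solveMOFBA()` computes the
front exactly (up to a numerical tolerance) by outer approximation:

1. Solve the $k$ single-objective problems and an equal-weights problem;
   each weighted-sum LP is followed by a lexicographic second stage that
   maximizes total growth while holding the weighted optimum *exactly* (an
   equality row), so returned points are efficient even for weights with
   zero entries.
2. Build the upper image of the points found so far (their convex hull minus
   the non-negative orthant). For $k \le 3$ its facets are enumerated
   directly from point triples, with downward-shifted point copies supplying
   the vertical facets.
3. Every inner facet normal is a candidate weight vector: if its weighted-sum
   LP improves on the facet offset, the new efficient point is added and the
   hull refined; otherwise the facet is confirmed as a supporting hyperplane
   of the true front. The confirmation threshold is kept near solver
   precision ($10^{-9}$ scale-relative): confirming at a looser tolerance
   would let vertices drift by that tolerance divided by the smallest weight
   component.
4. On termination the outer polytope (intersection of confirmed halfspaces)
   coincides with the inner hull; vertices are deduplicated at $10^{-6}$
   (scale-relative, lexicographic ordering) and non-extreme or dominated
   points are removed by small LPs.

Growth objectives are assumed non-negative and bounded; an unbounded strain
objective stops the computation with the strain named, rather than being
reported as a recession ray. Scalarizations are exported on their own:
`weightedSum()` (efficient by convexity), `epsilonConstraint()` (weakly
efficient), and `verifyFront()` cross-checks a front against random
weighted-sum samples.

Because near-degenerate vertices closer than the $10^{-6}$ deduplication
tolerance are merged, a front reported with $m$ vertices may stand for
$m + $ (merged duplicates) in exact arithmetic; the tolerance is the
documented meaning of "vertex count".

## MO-FVA and the front mesh

`mofvaAtPoint()` ranges each reaction subject to the componentwise floors
$C^\top v \ge \alpha f^*$ — every member must retain the fraction $\alpha$
of *its own* coordinate of the Pareto point $f^*$. The vector (rather than
scalar) form is deliberate: it preserves the per-member character of the
front. A zero coordinate makes that member's floor vacuous. $\alpha$
defaults to 0.9.

For three-member communities `meshFront()` places a barycentric lattice with
$n$ subdivisions — $(n{+}1)(n{+}2)/2$ points — on the triangle spanned by the
three single-member-optimal vertices. Two modes exist because the front
generally bulges above that triangle: `"flat"` (default) keeps the points on
the anchor triangle, which is always feasible by convexity and makes meshes
comparable across models; `"lifted"` raises each point onto the Pareto
surface by maximizing total growth above componentwise floors.
`aggregateRegions()` splits the triangle into $r^2$ congruent sub-triangles
($r(r{+}1)/2$ upward, $r(r{-}1)/2$ downward; points on cell edges are
assigned by a deterministic floor rule) and averages member-point maxima and
minima per region; a resolution whose cells catch no mesh point is an error,
not a silent gap. At full resolution ($n = 100$, $r = 15$) this yields the
5 151-point, 225-region description used for surface maps; tests and the
acceptance script run the same code at $n = 5$–$10$, which exercises every
branch at a fraction of the LP count.

## Thermodynamic ranking

Each exchanged metabolite carries a chemical potential
$\mu_i = \mu_i^0 \pm dg_i$ with $dg_i = R\,T\ln(x_i/x_i^0)$ the half-width
induced by the allowed concentration range ($R = 8.314$ J·mol$^{-1}$K$^{-1}$).
The chemical motive force $\mathrm{cmf} = \sum_i \mu_i v_i$ is taken over the
pool-to-environment boundary fluxes oriented *uptake-positive*: it measures
the external chemical potential consumed to drive the internal
non-equilibrium steady state, and larger values mark thermodynamically
favored states.

Within MO-FVA flux boxes $[a_i, b_i]$ and potential boxes the maximization
separates per metabolite, so `maximizeCmf()` enumerates the four products of
interval endpoints per metabolite — exact, and trivially an upper bound for
any feasible $(\mu, v)$. The `"numeric"` method re-solves each per-metabolite
block with box-constrained quasi-Newton ascent (L-BFGS-B) from the four
corners and the midpoint; it is retained purely as a cross-check and agrees
with corner enumeration to $10^{-6}$ relative on random instances. Per-block
multistart matters: a bilinear product on a box is a saddle surface whose
ascent paths can stall on the wrong corner from a single start.

## The synthetic generators

`makeCompetition()` builds $k$ strains drawing one pooled nutrient
(environment uptake cap `cap`), strain $j$ converting it to biomass with
yield $y_j$; the front is the simplex $\sum_j f_j/(y_j\,\mathrm{cap}) \le 1$
in closed form, which anchors the solver tests. `makeCrossfeed()` adds an
obligate producer-to-consumer dependency (consumers grow only on the
producer's exported acid; cyclic feeding specifications are rejected).
`randomCommunity()` generates seeded strains around a guaranteed
substrate-to-biomass chain plus mass-conserving side reactions, so models are
feasible and bounded by construction and reproducible from a single integer
seed; no global RNG state is left behind.

These generators emulate the *structure* of community models — shared pools,
capped environments, cross-feeding, degenerate optima — at a few dozen
reactions. They do not emulate genome-scale properties: thousands-reaction
networks, thermodynamically infeasible loops, nutrient-specific transporter
families, or curation noise. Tests passing on them certify the algorithms'
correctness on the model class, not predictive accuracy on any particular
real community.

## The hot-spring fixture

The packaged three-guild phototrophic mat community (SYN, a
*Synechococcus*-like oxygenic primary producer; FAP, a filamentous anoxygenic
phototroph; SRB, a sulfate-reducing bacterium) is a *synthetic
reconstruction*, marked as such in its file names: the full curated
genome-scale model of this ecosystem is not redistributable here, so the
package ships a reduced model built around three community-level budgets —
light energy, carbon and nitrogen, one unit each — with per-growth quotas

| budget | SYN | FAP | SRB |
|---|---|---|---|
| light energy (via photosynthate) | 1 | 1 | 73/89 |
| nitrogen (biomass content) | 1694/1755 | 1 | 54/65 |
| carbon (biomass content) | 11/27 | 35/46 | 1 |

SRB draws its energy budget indirectly: it grows only on acetate synthesized
from photosynthate by SYN (73/89 photon-equivalents per unit), so its growth
costs the community light even though it is no phototroph. The quotas are
exact rationals chosen once so that (i) each guild's solo FBA optimum is
exactly 1 h$^{-1}$ (every column's largest quota is 1) and (ii) the
community front is the polytope with the five vertices
$(1,0,0)$, $(0,1,0)$, $(0,0,1)$, $(0.27, 0, 0.89)$, $(0, 0.46, 0.65)$
characteristic of this ecosystem's reported trade-off structure — given the
vertices, the three budget facets (and hence the quota ratios) are determined
by plane geometry, and the package computes the front from the flux model at
run time rather than storing it. Biological detail retained around the
budgets: the Rubisco oxygenase/carboxylase flux ratio fixed at 0.03
(glycolate production, reflecting an anaerobic daytime state), nitrate
reduction tied to half of SYN's photon flux (ferredoxin re-oxidation, which
makes SYN an obligate ammonia exporter whenever it is photosynthetically
active — the source of the strictly positive ammonia-export minima near the
mixed vertices), acetate overflow as the lumped reduced-carbon currency,
reversible glycolate handling by FAP, and sulfate reduction to sulfide by
SRB. Environment caps beyond the three budgets (nitrate, sulfate, CO$_2$)
are set generously so they never bind.

The thermodynamic table is equally a calibrated reconstruction. Potentials
are expressed relative to an environmental reference basis rather than as
formation energies: water is the zero point, the photon potential
$\mu_{h\nu} = 68.6$ kJ·mol$^{-1}$ anchors the scale through the
glucose-synthesis relation ($6\,\mathrm{CO}_2 + 6\,\mathrm{H_2O}
\rightarrow \mathrm{C_6H_{12}O_6}$ driven by 48 photons at equilibrium,
which fixes the glucose entry), reduced carbon species carry positive
potentials (acetate 50, glycolate 40) and inorganic nutrients small negative
ones (CO$_2$ −25, nitrate −20, ammonia −30, sulfate −40, sulfide +20).
All species use $dg = R\,T\ln(10^3) \approx 20$ kJ·mol$^{-1}$ at 348.15 K
(75 °C), corresponding to concentrations free within $10^{-3}$–$10^{3}$ M of
reference, except water and photons whose concentrations are fixed
($dg = 0$). With these values the cmf surface over the front is positive
everywhere and maximal toward the high-SYN corner, with the SRB corner below
the FAP corner — the qualitative ordering expected for this mat — but the
absolute kJ·gDW$^{-1}$·h$^{-1}$ values are properties of the reconstruction,
not measurements.

## Numerical choices

* LP engine: dense bounded-variable two-phase primal simplex (compiled),
  Dantzig pricing with a Bland fallback after stalls, explicit basis inverse
  with periodic refactorization; feasibility tolerance $10^{-8}$, reduced-cost
  tolerance $10^{-9}$. Sized for the few-hundred-column models this package
  targets; it is validated against an independent implementation in the test
  suite, and the solve contract (`solveLP()`) isolates it so another backend
  could be swapped in.
* Default bounds for unbounded reactions: $\pm 1000$ mmol·gDW$^{-1}$·h$^{-1}$
  (the community convention in constraint-based modeling).
* $\alpha$-scaling of an optimum is refused when $z^* < 0$, since the
  inequality would invert its meaning; growth objectives are non-negative.
* Front tolerances: facet confirmation at $10^{-9}$ (scale-relative), vertex
  deduplication at $10^{-6}$, facet-support recomputation as exact maxima
  over the vertex set so every reported vertex satisfies every reported
  inequality by construction.
* Mesh region assignment uses floor with an $10^{-9}$ guard and assigns
  edge points to the lower-index cell, deterministically.

## Limitations

* Front meshing and regional aggregation are implemented for exactly three
  objectives; fronts themselves are computed for any $k$, but facet
  enumeration is exhaustive over point tuples and intended for $k \le 3$.
* The cmf treatment ranks states after MO-FVA; it does not impose
  thermodynamic constraints inside the LP (no concentration variables), does
  not include biomass-concentration terms, and its absolute scale on the
  fixture is synthetic (above).
* The SBML importer covers level-3 core plus the flux-bounds/objective
  subset of the FBC package that constraint-based models actually use; it is
  not a general SBML toolkit. External metabolites are recognized by
  compartment naming (`e`, `ext`, `external`, `pool`, or a `_e` suffix).
* Flux units are whatever the model's bounds are expressed in; the package
  never rescales.
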