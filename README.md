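# MOFBA — multi-objective constraint-based analysis of microbial communities

Microbial communities are shaped by trade-offs: when one member grows faster
it consumes nutrients that other members need, or produces by-products that
feed them. Classical flux balance analysis (FBA) cannot express this — it
optimizes a *single* objective, so modeling a community forces an arbitrary
choice of "community objective". MOFBA instead keeps one growth objective per
member and computes the **entire Pareto front** of simultaneously achievable
growth rates, together with the flux variability and thermodynamic ranking of
states on that front.

The package is aimed at systems-biology and microbial-ecology researchers who
have per-organism metabolic reconstructions (stoichiometric matrices with
flux bounds) and want quantitative, assumption-light predictions of community
composition.

## The model

Each strain *l* is a constraint-based model: stoichiometric matrix
**S**ˡ, steady state **S**ˡ**v** = 0, flux bounds *l* ≤ **v** ≤ *u*, and a
growth objective **c**ₗ. The community matrix **S**^σ places the strain
matrices in diagonal blocks and adds a *pool* compartment: one extra row per
shared metabolite that mirrors (with flipped sign) every strain exchange of
that metabolite, plus one pool↔environment exchange column. Steady state
applies to the pool rows too, so all cross-feeding is routed through the pool
and capped by the environment exchange bounds.

* **MO-FBA** solves the multi-objective linear program
  max (**c**₁ᵀ**v**, …, **c**ₖᵀ**v**) subject to **S**^σ**v** = 0 and bounds.
  Its solution is the Pareto front, computed exactly (vertices + facet
  inequalities) by an outer-approximation scheme of the Benson type driven by
  weighted-sum LPs.
* **MO-FVA** explores flux variability near a Pareto point **f**\*: for each
  reaction it minimizes/maximizes the flux subject to the componentwise
  constraint **C**ᵀ**v** ≥ α·**f**\* (default α = 0.9).
* **Thermodynamic ranking** maximizes the chemical motive force
  cmf = Σᵢ μᵢ·vᵢ over the MO-FVA exchange-flux ranges and the potential boxes
  μᵢ⁰ ± dgᵢ, where dg = R·T·ln(x/x⁰) reflects the allowed concentration
  range. The box problem separates per metabolite and is solved exactly by
  corner enumeration (a quasi-Newton optimizer is kept as a cross-check).

The LP engine is a compiled bounded-variable two-phase simplex shipped with
the package (`solveLP()`), validated in the test suite against an independent
pure-R implementation.

## Worked example

Two strains compete for one pooled nutrient (uptake capped at
10 mmol/gDW/h) with biomass yields 1 and 0.5 h⁻¹ per unit nutrient:

```r
library(MOFBA)
toy <- makeCompetition(yields = c(1, 0.5), cap = 10)
solveMOFBA(toy$model)
#> ParetoFront in 2 objective(s): 2 vertex/vertices, 3 facet(s)
#>      S1 S2
#> [1,] 10  0
#> [2,]  0  5
```

The front is the simplex f₁/10 + f₂/5 ≤ 1: any growth-rate pair under that
line is achievable, and giving strain 2 one unit of growth always costs
strain 1 two units.

The packaged three-guild hot-spring mat model (SYN, a *Synechococcus*-like
primary producer; FAP, a filamentous anoxygenic phototroph; SRB, a
sulfate-reducing bacterium; a synthetic reduced reconstruction, see the
vignette) shows a richer trade-off structure:

```r
hs <- loadHotSpringFixture()
solveMOFBA(hs$community)
#> ParetoFront in 3 objective(s): 5 vertex/vertices, 11 facet(s)
#>       SYN  FAP  SRB
#> [1,] 1.00 0.00 0.00
#> [2,] 0.27 0.00 0.89
#> [3,] 0.00 1.00 0.00
#> [4,] 0.00 0.46 0.65
#> [5,] 0.00 0.00 1.00
```

Each guild alone can grow at 1 h⁻¹, and the mixed vertices show that total
community growth peaks (1.16 h⁻¹) when SYN grows *below* its optimum while
feeding SRB. MO-FVA at 90% of the SYN/SRB vertex shows that the ammonia
exchange of SYN has a strictly positive minimum — the producer is an obligate
ammonia exporter there:

```r
fluxRanges(mofvaAtPoint(hs$community, c(0.27, 0, 0.89), alpha = 0.9,
                        reactions = "SYN:EX_nh3"))
#>     reaction      vmin      vmax
#> 1 SYN:EX_nh3 0.1689219 0.2654462
```

`runPipeline()` chains the stages (front → mesh → MO-FVA → regional
aggregates → cmf surface) and writes TSV/JSON artifacts; the thin CLI at
`inst/exec/mofba` exposes the same steps as `build`, `fba`, `fva`, `mofba`,
`mofva`, `thermo`, `synth` and `run` subcommands.

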