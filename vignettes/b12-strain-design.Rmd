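---
title: "Constraint-based strain design for cobalamin production: models, screens and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based strain design for cobalamin production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b12flux)
```

## The model

`b12flux` treats a metabolism as a stoichiometric network: metabolites,
reactions with signed coefficients, and flux bounds in mmol/gDW/h. Flux
balance analysis (FBA) assumes the cell is at steady state — every internal
metabolite's production equals its consumption, `S v = 0` — and that the flux
distribution maximizes a stated objective. The optimum of

$$\max_{v} \; c^\top v \quad \text{s.t.} \quad S v = 0, \;\; \ell \le v \le u$$

is a prediction of the best the network can do under those constraints: the
growth rate when the objective is the biomass pseudo-reaction, or the
attainable cobalamin synthesis rate when the objective is the terminal
assembly step of the pathway (adenosylcobinamide-GDP ribazoltransferase,
EC 2.7.8.26). FBA ignores kinetics and regulation entirely: no enzyme
saturation, no riboswitch feedback, no expression cost. What it predicts is a
stoichiometric ceiling, which is exactly the quantity the screens compare
across genetic interventions.

Two modeling conventions matter for correctness:

* **Exchange reactions and uptake signs.** Boundary reactions have a single
  metabolite; negative flux through them is uptake. A growth medium is
  applied by setting each mapped exchange's *lower* bound to minus the
  measured consumption rate. The compound-to-exchange mapping is explicit in
  the medium file (`EX_glc__D_e` for glucose, and so on) because silent name
  matching is the main way medium application goes wrong across model
  versions. By default unlisted exchanges keep the base model's bounds — the
  medium states only what was measured; `strict = TRUE` closes every other
  uptake first for sensitivity analyses.
* **A drain for the product.** At steady state, flux can only enter a
  terminal metabolite if something removes it. `prepare_product_objective()`
  therefore adds a demand reaction for any dead-end product of the objective
  reaction before solving. Without it the production optimum is identically
  zero — a modeling artifact, not a biological prediction.

## Curation and the knockin screen

The cobalamin pathway of the *P. putida* KT2440 reconstruction iJN1463 is
incomplete: three activities present in the genome (cobyrinate a,c-diamide
synthase EC 6.3.5.9, aerobic 5,6-dimethylbenzimidazole synthase
EC 1.13.11.79, precorrin-3B synthase EC 1.14.13.83) are missing or unnamed.
The `base_curation` bundle restores them. EC 2.5.1.17 (cob(I)alamin
adenosyltransferase) is deliberately *not* part of the curation set: it is
already represented in the reconstruction under its updated annotation, so
adding it again would duplicate an existing column.

Knockin candidates are further bundles: the two-reaction aminopropanol
linker (threonine kinase EC 2.7.1.177 + threonine-phosphate decarboxylase
EC 4.1.1.81), ALA synthase of the C4 route (EC 2.3.1.37), threonine
3-dehydrogenase (EC 1.1.1.103) and glycine C-acetyltransferase
(EC 2.3.1.29). Their stoichiometries are data, not code
(`inst/extdata/reactions/kegg_specs.yaml`), recorded with KEGG reaction ids
as provenance; cofactor usage is simplified where KEGG lists alternatives,
and users can amend the YAML without touching the engine. New metabolites
introduced by a spec are created in the cytosol unless their id carries a
compartment suffix, since all of the pathway chemistry involved is
cytosolic. Bundle application is copy-on-write and id-sorted, so the final
model is independent of bundle order and screens over many variants cannot
interfere with each other.

A designed property of the toy networks, and an expected regression on real
models, is that knockins are growth-neutral: added production reactions do
not touch the biomass branch, so the biomass optimum is unchanged across
knockin variants. Production itself is *not* monotone under knockins — two
added routes competing for the same precursor pool can lower the
production-maximizing optimum relative to either alone — so the suite only
asserts monotonicity where it genuinely holds: adding a reaction can never
decrease a fixed maximized objective, and deletions can never increase it.

## The deletion screen

The deletion screen is exhaustive by design: all subsets of sizes 1 to 5 of
the 12 candidate reactions, `sum(choose(12, 1:5)) = 1585` evaluations with
two LP solves each. Exhaustive enumeration (rather than a genetic-algorithm
search) is the right tool at this scale — it is complete, deterministic and
cheap. Candidates are named by EC number; a compound entry such as
`1.8.1.4-1.2.4.2` (or `/`-separated) is one candidate slot whose alternative
annotations are matched together, and a candidate matching several model
reactions deletes all of them at once — the conservative reading of
reaction-level deletion. Results are ranked by production value descending
with a fully deterministic tie-break (biomass descending, then smaller
subsets first, then label), so two runs of the same screen are
byte-identical.

## The benchmark

Fermentation outcomes are compared on the specific-productivity scale,
umol/gDW/h: `(mg/L / g/mol) * 1000 / (gDW/L) / h`. The shipped reference is
the *P. denitrificans* SC510 fermentation (214 mg/L over 168 h at
33.23 gDW/L). The molar mass defaults to cyanocobalamin, 1355.37 g/mol — the
commercially assayed form — and is overridable per record for other
cobalamin species. `fold_change()` and `percent_increase()` are kept as
separate, input-validated operations so that reported comparisons are always
traceable to two explicit rates on the same scale.

## The LP engine and numerical choices

No LP solver is assumed as a dependency: the engine is a bounded-variable
two-phase primal simplex implemented in the package. Design points:

* **Bounds are handled implicitly** (nonbasic variables sit at either bound,
  and the ratio test allows bound flips), so the basis never exceeds the
  number of metabolites — the natural shape for FBA, where `n` reactions
  greatly exceed independent rows of `S`.
* **Anti-cycling** by Bland's rule (smallest-index entering and leaving
  variable). Degenerate vertices are routine in flux polytopes; Bland
  guarantees termination at a modest cost in iteration count, which is
  irrelevant at the problem sizes the package targets.
* **Tolerances.** Pivot/feasibility tolerance `1e-9`; a solution is accepted
  as optimal only if the steady-state residual `max |S v|` is at most
  `1e-6` and bounds hold within `1e-9` (violations warn). Reported optima
  are compared at `1e-6`, far below the three decimals at which yields are
  quoted.
* **Only the objective value is contract-stable.** Flux polytopes routinely
  have alternate optima; repeated solves return the same optimum but may
  return different vertices. No test, report or screen ranks on individual
  fluxes of a degenerate solution.
* **Degenerate inputs.** Infeasible and unbounded problems are reported as
  such (all model bounds are finite at ±1000 mmol/gDW/h, the community
  convention, so unboundedness only arises from user-supplied infinite
  bounds); an empty knockout set, an empty medium and an empty bundle list
  are exact identities.

The engine is validated along two independent routes: exhaustive vertex
enumeration of the flux polytope (rank-reduced basis enumeration with bound
combinations, feasible for networks of up to ~10 reactions) and
`boot::simplex` as a second LP implementation; the SBML/JSON writers are
additionally cross-read by cobrapy, whose own solver reproduces the optima.

## The toy generator: what it does and does not emulate

`make_toy_model()` builds the minimal topology the analysis logically relies
on: an uptake-limited precursor, a linear multi-step product pathway with a
terminal demand, a competing branch draining the shared precursor (capacity
and optionally a forced flux), an optional knockin bypass supplying extra
precursor, and a biomass branch fed by its own substrate. Every optimum is
known in closed form — product = uptake − forced + bypass, biomass =
biomass uptake, independent of the product side — so the solver and both
screens are checked against analytic expectations, not against themselves.
Coefficients are small integers, keeping LP vertices exactly representable
in floating point. The `seed` only permutes storage order; the network
itself is fully determined by the spec, so screens have exact expected
outputs. A spec whose forced competitor flux exceeds its capacity or the
uptake rate is rejected at construction.

`make_random_network()` provides seeded, connected, mass-balanced networks
(a deterministic chain backbone plus random 1:1 conversions, all bounds
finite) for property-style tests. A connected network with one uptake and
one export needs at least `n_metabolites + 1` reactions — the chain backbone
alone uses that many — so smaller reaction budgets are rejected as
unsatisfiable.

What the toys deliberately do not emulate: cofactor coupling, gene–protein–
reaction logic, compartmentalization, kinetic and regulatory effects
(including the B12 riboswitches that motivate the companion genetic
strategy). Passing tests therefore demonstrate the correctness of the LP,
the edits, the screens and the bookkeeping — not that a genome-scale
prediction is biologically right. Genome-scale claims additionally depend on
the reconstruction, the curation stoichiometries and the measured uptake
rates fed to the medium module.

## Problem sizes and determinism in the shipped suite

The test suite runs entirely on generated networks: toys of 6–15 reactions,
random networks of 2–6 metabolites and up to 12 reactions (100 seeds for the
boundedness property), deletion screens over 3 planted candidates
(7 subsets), and vertex-enumeration cross-checks on networks of at most 8
reactions — a few hundred LP solves in a few seconds. The acceptance script
mirrors these sizes and takes its RNG seed on the command line; everything
except the seeded random networks is deterministic by construction. The full
1585-subset screen on a curated genome-scale model (3170 LP solves) is
supported through the same code path via `reproduce_workflow()` and is
bounded by the LP engine's dense-solve cost per iteration; it is not part of
the shipped tests, which require no model downloads.

## Known limitations

* FBA optima are stoichiometric ceilings under the stated uptakes, not rate
  predictions; regulation (notably B12 riboswitch feedback) is out of scope.
* The curation stoichiometries are KEGG-derived simplifications; users with
  better evidence should edit the YAML bundle library.
* The SBML reader/writer covers the FBC v2 constraint-based subset (species,
  reactions, parameterized bounds, one active maximization objective, EC
  annotations); kinetic laws, events and unit definitions are ignored.
* The dense simplex targets small-to-medium networks; genome-scale solves
  work but are slow compared to sparse production LP codes.
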