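# b12flux

Constraint-based strain design for vitamin B12 (cobalamin) production in
*Pseudomonas putida* KT2440.

Cobalamin is among the most complex cofactors a cell can build (~30 enzymatic
steps through porphyrin metabolism), and industrial production still relies on
slow-growing, hard-to-engineer strains such as *Pseudomonas denitrificans*.
`b12flux` implements the in silico side of evaluating *P. putida* KT2440 — a
fast-growing, GRAS, genetically tractable chassis — as an alternative host:
it curates a genome-scale metabolic model of the cobalamin pathway, predicts
growth and production yields by flux balance analysis, screens candidate
knockins and exhaustive multi-reaction deletions, and benchmarks the predicted
yields against fermentation data. It is aimed at metabolic engineers and
systems biologists working with BIGG/SBML genome-scale models.

## The method

Flux balance analysis solves the linear program

```
max  c' v        (flux of the objective reaction)
s.t. S v = 0     (steady state: no net accumulation of any metabolite)
     lb <= v <= ub
```

where `S` is the stoichiometric matrix (metabolites x reactions), `v` the
flux vector in mmol/gDW/h, and the bounds encode reaction reversibility,
knockouts (`lb = ub = 0`) and the growth medium (uptake rates as exchange
lower bounds, uptake-negative convention). Two objectives are used
throughout: the biomass pseudo-reaction (growth), and the terminal cobalamin
assembly step, adenosylcobinamide-GDP ribazoltransferase (EC 2.7.8.26), as
the production objective — with a demand reaction added for its product so
steady state cannot silently force zero production.

On top of the LP sit the two strain-design screens:

* **knockin screen** — curation bundles (heterologous reactions with
  KEGG-derived stoichiometry: the aminopropanol linker EC 2.7.1.177 +
  4.1.1.81, ALA synthase EC 2.3.1.37, and others) are added in
  combinations, and both objectives are re-solved per variant;
* **deletion screen** — all 1585 subsets of sizes 1–5 of 12 EC-annotated
  candidate reactions around the porphyrin pathway are knocked out
  exhaustively, both objectives solved per subset, results ranked
  deterministically.

The benchmark module converts fermentation outcomes to specific
productivity, e.g. 214 mg/L of B12 over 168 h at 33.23 gDW/L (the
*P. denitrificans* SC510 reference) to
`(214 / 1355.37) * 1000 / 33.23 / 168 = 2.83e-2` umol/gDW/h.

The LP engine is a bounded-variable two-phase simplex written in the package
(no LP backend is assumed); it is cross-validated in the test suite against
exhaustive vertex enumeration of the flux polytope, `boot::simplex`, and
cobrapy reading the package's own SBML/JSON output.

## Worked example

```r
library(b12flux)

# a toy network with a 10 mmol/gDW/h precursor supply, a competing branch
# forced to drain 4, and the product demand as the production objective
toy <- make_toy_model(toy_spec(uptake_rate = 10, competitor_forced = 4,
                               competitor_capacity = 5))
summary(toy$model)
#> Metabolic model 'toy_b12': 6 metabolites, 9 reactions (5 boundary, 1 EC-annotated), 1 compartment(s)
#> objective: BIOMASS

sol <- solve_fba(toy$model, toy$product_objective)
print(sol)
#> FBA solution (toy_b12, objective DM_prod_c)
#>   status:    optimal
#>   optimum:   6 mmol/gDW/h
#>   residual:  0
```

The optimum is 6: of the 10 units of precursor uptake, 4 are lost to the
forced competing branch. Deleting that branch recovers them:

```r
res <- run_deletion_screen(toy$model, medium_spec(),
                           list(deletion_candidate("competitor", "9.1.1.1")),
                           max_size = 1, product_objective = "DM_prod_c")
res[, c("intervention", "size", "biomass", "b12_umol")]
#>   intervention size biomass b12_umol
#> 1   competitor    1       5    10000
```

(`b12_umol` is on the umol/gDW/h scale, hence 10 mmol/gDW/h prints as 10000;
biomass is untouched because the toy's growth branch is independent.)
Benchmarking a predicted yield against the SC510 fermentation:

```r
ref <- specific_productivity(sc510_record())
fold_change(0.400, ref)
#> benchmark 0.0283 umol/gDW/h; fold change of a 0.400 yield: 14.1
```

Genome-scale models work the same way: `load_model("iJN1463.json")` (or the
SBML file), `apply_bundles(model, "base_curation")`, `b12_medium()` for the
shipped six-compound fermentation medium, then `solve_fba()`,
`run_knockin_screen()` and `run_deletion_screen()`, or everything at once via
`reproduce_workflow(model, out_dir = "reports")`. A thin command-line front
end with subcommands `fba`, `knockin`, `delscan`, `benchmark`, `synth` and
`reproduce` ships at `inst/cli/b12flux.R`.

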