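# strainscope

Constraint-based analysis and comparison of bacterial genome-scale
metabolic models, built for the workflow used to refine and compare
strain-level reconstructions of *Lactobacillus casei*: predict growth by
flux balance analysis (FBA), screen amino-acid requirements and
carbohydrate utilization in silico, score the predictions against observed
phenotype tables, curate the network (mass/charge balance, detection of
free-ATP cycles), repair missing capabilities by minimal gap-filling, and
pinpoint functional differences between two strains by differential gene
deletions.

## Who this is for

Microbial systems biologists working with strain-level metabolic
reconstructions (SEED/COBRA-style models in SBML or plain reaction tables)
who need a tested, scriptable pipeline for the classic
screen–gapfill–rescreen–compare loop, in R, with no solver dependencies:
the linear and mixed-integer programs are solved by a bounded-variable
simplex and branch-and-bound core inside the package.

## The science in brief

FBA finds a steady-state flux distribution maximizing the biomass
pseudo-reaction flux µ (1/h):

    max  c'v   s.t.   S v = 0,   lb ≤ v ≤ ub

where `S` is the stoichiometric matrix and the growth medium sets the
uptake (lower) bounds of exchange reactions. Gene deletions act through
boolean gene-protein-reaction (GPR) rules: a reaction whose rule evaluates
false loses its flux. On top of this the package implements:

* **Phenotype screens** — omit one amino acid at a time (µ < ε ⇒ the amino
  acid is required), or add one carbohydrate at a time to an
  essential-amino-acid medium (µ rises ⇒ the carbohydrate is usable), with
  accuracy scoring (false positive = growth predicted, none observed).
* **Network QC** — per-reaction elemental/charge balance from Hill-notation
  formulas, and detection of thermodynamically infeasible cycles: with all
  exchanges closed, any positive ATP-dissipation flux proves the network
  makes ATP from nothing; a minimal witness set of cycle reactions is
  extracted and directionality fixes are suggested.
* **Minimal gap-filling** — a MILP choosing the fewest database reactions
  whose addition restores growth under a condition where growth is
  observed, with integer-cut enumeration of alternative minimal sets.
* **Two-model comparison** — enumerate deletions of ortholog pairs and
  unique genes, keep the minimal sets lethal in exactly one model, and
  classify each difference as genetic (isozyme complement), orthology
  (equivalent genes not mapped as orthologs) or metabolic (reactions unique
  to one network).
* **Synthetic benchmarks** — deterministic generators for all of the above
  with planted, provable truths, including stand-in models for the two
  *L. casei* strains that encode their published genotype-level differences
  (the stand-ins are synthetic; see the vignette for exactly what they do
  and do not represent).

## Worked example

```r
library(strainscope)

## a toy network with a known optimum
toy <- make_core_toy()
fba(toy$model, medium = toy$medium)
#> <fba_solution> model TOY-CORE, objective BIOMASS
#>   status optimal, value 10
```

µ = 10/h is the closed-form bottleneck: 10 mmol/gDW/h glucose yields 2 ATP
each, and biomass needs 2 ATP per unit of growth.

```r
## amino-acid requirement screen on the synthetic 12A strain stand-in
bundle <- synthetic_strain_models()
calls <- scan_amino_acids(bundle$l12a, bundle$media$cdm,
                          bundle$amino_acid_exchanges)
score_predictions(calls, stats::setNames(bundle$observed$amino_acids$l12a,
                                         bundle$observed$amino_acids$compound))
#> <accuracy_report> amino_acid screen, model sLca12A
#>   accuracy 19/20 (FP 1, FN 0)
#>   discrepancies: glu (pred NR, obs R)
```

The screen closes one amino-acid exchange at a time and re-solves FBA. The
single error is glutamate: the model converts glutamine to glutamate
(EC 2.6.1.16), so it predicts growth without glutamate uptake although the
strain requires it — the known residual discrepancy of the 12A model.

```r
## minimal gap-filling on a planted single-gap scenario
gs <- make_gap_scenario(1, decoys = 8)
gapfill(gs$model, gs$database, gs$medium, max_solutions = 2)
#> <gapfill_result> status filled, target growth 0.5, 2 solution(s)
#>   #1 [1 rxns, mu 10, minimal]: GLY
#>   #2 [2 rxns, mu 10, minimal]: GLYB1, GLYB2
```

The MILP recovers the removed reaction as the unique size-1 fill and the
planted two-reaction bypass as the alternative.

```r
## differential gene deletions between the two strain stand-ins
compare_models(bundle$atcc334, bundle$l12a, bundle$orthologs,
               bundle$media$compare_essential, max_set_size = 1)
#> <model_comparison> sLca334 vs sLca12A: 5 differential deletion set(s) (102 units, sets up to size 1)
#>   {L334_mthfd~L12A_mthfd}: lethal in A (mu_A 0, mu_B 1.92), metabolic; rescue: PANt, EX_pan_e
#>   {L334_pyk~L12A_pyk}: lethal in A (mu_A 0, mu_B 1.94), genetic; rescue: PYK
#>   {L334_t_glu~L12A_t_glu}: lethal in B (mu_A 1.94, mu_B 2.78e-16), metabolic; rescue: GDH
#>   {L334_ldh}: lethal in A (mu_A 0, mu_B 1.94), orthology; rescue: LDH
#>   {L12A_ldh}: lethal in B (mu_A 1.94, mu_B 0), orthology; rescue: LDH
```

The first row is the folate-motif difference: deleting
5,10-methylene-THF dehydrogenase (EC 1.5.1.5) kills the ATCC 334 stand-in,
while 12A reroutes through EC 2.1.2.11 + formate:THF ligase and survives
because only it can export the pantothenate by-product (`PANt`). Under the
all-amino-acid condition this set disappears and the remaining sets are a
subset of those above.

A command-line front end covering the same stages ships in
`inst/scripts/strainscope.R` (subcommands `fba`, `qc`, `screen`, `gapfill`,
`compare`, `simulate`, `reproduce`).

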