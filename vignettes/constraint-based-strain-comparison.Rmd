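---
title: "Constraint-based refinement and comparison of strain-level metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based refinement and comparison of strain-level metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainscope)
```

## The modelling framework

A genome-scale metabolic model is a stoichiometric network: metabolites in
two compartments (cytoplasm and extracellular space), reactions with flux
bounds in mmol/gDW/h, and boolean gene-protein-reaction (GPR) rules that say
which genes must be present for each reaction's enzyme to exist (AND =
complex subunits, OR = isozymes). Flux balance analysis (FBA) treats the
cell as a steady-state flux machine: it maximizes the flux through a biomass
pseudo-reaction — whose value is the growth rate µ in 1/h — subject to mass
balance `S v = 0` and the flux bounds,

$$\max_v \; c^\top v \quad \text{s.t.} \quad S\,v = 0, \;\; lb \le v \le ub,$$

where the growth medium enters through the lower bounds of the exchange
reactions (negative flux = uptake, positive = secretion). `strainscope`
implements this workflow end to end: model I/O (SBML Level 3 + fbc, SEED-era
Level 2, and a plain tabular format), FBA with gene knockouts, curation
checks (mass/charge balance, detection of thermodynamically infeasible
ATP-generating cycles), minimal gap-filling against a reaction database,
in-silico phenotype screens scored against observed tables, and a
differential gene-deletion comparison of two strain models.

All linear programs are solved by a bounded-variable two-phase revised
simplex implemented in the package, with a branch-and-bound layer for the
integer programs (gap-filling, cardinality witnesses). The test suite checks
the simplex against exhaustive vertex enumeration and each combinatorial
routine against brute-force search, so every optimization result exercised
here has an independently computed twin.

## Tunable parameters

* **Growth threshold** `growth_eps()` = 1e-6 h⁻¹. LP solvers return tiny
  nonzero optima on numerically degenerate problems, so "no growth" means
  µ below this threshold, never exactly zero.
* **Default flux bounds**: (−1000, 1000) mmol/gDW/h for reversible
  reactions, (0, 1000) for irreversible ones, the convention used across
  constraint-based tooling, applied whenever an input file carries no
  explicit bounds.
* **Default uptake rate** 10 mmol/gDW/h per medium compound. This is a
  stand-in: the chemically defined medium used for the published strain
  experiments specifies per-compound rates in a supplement that is not
  distributed with this package, so a single uniform cap is used and all
  growth rates are interpreted qualitatively (growth vs no growth), never
  as quantitative rate predictions.
* **Carbohydrate call threshold** δ = max(1e-6, 0.01·µ₀): a carbohydrate is
  called usable when growth rises above the carbohydrate-free baseline µ₀
  by more than δ. The relative guard absorbs solver noise when µ₀ > 0.
* **Gap-fill growth target** = max(ε, 0.05 × the growth rate attained with
  the entire candidate database added). The threshold the original
  gap-filling studies used is unstated; 5% of the best attainable rate
  demands a biologically meaningful fill without requiring full recovery.
* **Weak growth (W) scoring**: observed W counts as growth, so predicting
  "not required"/"growth" against a W observation is correct. This mirrors
  how the published accuracy rows treat aspartate (observed W, predicted
  NR, not counted as a discrepancy). The alternative policy is available
  as `w_policy = "no_growth"`.

## The two-model comparison

The comparison enumerates *deletion units* — an ortholog pair (deleted
jointly, one gene in each model) or a gene unique to one model — in sets of
up to `max_set_size` units, keeps the minimal sets lethal in exactly one
model (µ < ε on one side, µ ≥ ε on the other), and classifies each:

1. **genetic** — every reaction disabled in the dying model has a same-id
   counterpart in the survivor kept alive by extra isozyme genes;
2. **orthology** — the rescuing genes do the same job as deleted genes but
   were never paired in the ortholog map, so the joint deletion missed
   them;
3. **metabolic** — the survivor reroutes through reactions the other model
   simply does not have.

The original formulation of this comparison is a bilevel MILP; at the
network sizes exercised here exhaustive enumeration with superset pruning
produces identical results (the suite proves this against unpruned brute
force) and is far easier to verify, so enumeration is the implementation
and the bilevel duality machinery is out of scope. Category precedence is
genetic > orthology > metabolic so each set gets one label. Counts of
differential sets depend on the size cap and candidate filtering; they are
reported, not treated as universal constants.

## What the synthetic data emulate

`make_core_toy()` is a 12-metabolite, 14-reaction fermentative network with
a closed-form optimum (µ = min(glucose cap, 2 × amino-acid cap)), a planted
auxotrophy and a planted synthesis route; its randomized variants only move
uptake capacities within ranges that keep the closed form valid.
`make_futile_cycle_model()`, `make_gap_scenario()` and
`make_paired_models()` plant, respectively, an ATP-generating loop with a
known witness, pathway gaps with known minimal fills plus dead-end decoys,
and paired models differing in exactly one genetic / orthology / metabolic
feature. Every generator returns a truth manifest from which its expected
output can be derived mechanically.

`synthetic_strain_models()` builds stand-in models for *Lactobacillus
casei* ATCC 334 and 12A. These are **not** the published genome-scale
reconstructions (hundreds of genes and ~1000 reactions each, distributed as
journal supplements); they are small networks that encode the
genotype-level facts reported for the strains:

* no biosynthesis routes for arginine, the branched-chain amino acids
  (isoleucine, leucine, valine) and the aromatic amino acids
  (phenylalanine, tryptophan, tyrosine) — the seven experimentally
  essential amino acids;
* glutamate synthesizable from glutamine in both strains via
  glucosamine-fructose-6-phosphate aminotransferase (EC 2.6.1.16), which
  makes both models predict glutamate non-essential — the one residual
  error of the 12A model, whose in-vivo requirement is absolute; a de-novo
  glutamate route exists only in the ATCC 334 stand-in;
* strain-specific carbohydrate machinery: transport and catabolism for
  D-raffinose, panose and pullulan only in 12A, and a complete
  myo-inositol pathway in 12A (the known false positive — the strain does
  not grow on it in vivo, presumably for regulatory reasons FBA cannot
  see);
* the folate motif: serine hydroxymethyltransferase feeds
  5,10-methylene-THF, which 5,10-methylene-THF dehydrogenase (EC 1.5.1.5)
  oxidizes toward 10-formyl-THF for purine synthesis. Both stand-ins also
  carry the alternative route — 5,10-methylene-THF:3-methyl-2-oxobutanoate
  hydroxymethyltransferase (EC 2.1.2.11) plus formate:THF ligase
  (EC 6.3.4.3), with the pantoate steps (EC 1.1.1.169, 3.5.1.22) draining
  the by-product to pantothenate — but only 12A has the pantothenate
  exporter (carrying no gene association). Deleting the dehydrogenase is
  therefore lethal only in the ATCC 334 stand-in, and only when glycine
  must be made rather than imported, which is why the difference appears
  under the essential-amino-acid condition and disappears when all amino
  acids are supplied;
* an extra pyruvate-kinase isozyme in 12A (a genetic difference) and
  deliberately unmapped lactate-dehydrogenase genes (an orthology
  difference).

Because the screens *compute* phenotypes from this topology by FBA, the
accuracy rows against the observed in-vivo tables (20/20 and 19/20 amino
acids; 54/54 and 53/54 carbohydrates over the 54-compound panel: 26
compounds unusable by both strains plus the 28-row utilization table) are
genuine outputs of the pipeline. What passing these screens shows is that
the screening, scoring and comparison machinery recovers planted biology
exactly; it does not validate the published reconstructions themselves,
whose size, gene inventory (Table-style component counts) and exact
deletion-set counts cannot be reproduced without the supplementary model
files. Stoichiometries in the stand-ins are schematic (amino-acid synthesis
lumped to pyruvate units, no nitrogen/redox bookkeeping, most metabolites
without elemental formulas), so their balance reports are largely
"undetermined" by construction and the networks make no claim of elemental
realism.

## Numerical choices

* Simplex tolerances: 1e-9 on reduced costs and pivots, 1e-7 on phase-1
  feasibility; Dantzig pricing with a permanent switch to Bland's rule
  after a degeneracy stall, and basis refactorization every 60 pivots.
* Only µ is contract-bearing in FBA results: flux vectors are reported and
  checked for mass balance and bounds, but individual fluxes are never
  asserted (alternate optima are ubiquitous).
* Energy-cycle witnesses default to the L1-norm LP (deterministic, no
  integer program needed); the exact minimum-cardinality witness is
  available via `witness = "cardinality"`. Witnesses are diagnostics:
  `suggest_cycle_fixes()` proposes directionality restrictions but never
  mutates the model.
* Gap-fill enumeration uses cardinality integer cuts, so later solutions
  can never be supersets of earlier ones; every reported set of up to four
  reactions is re-verified minimal by exhaustive subset FBA.
* Unbounded objectives (possible on unbalanced drafts) are reported as
  status `"unbounded"`, never clipped.
* Problem sizes: the stand-in strain models have ~150 reactions each; the
  full comparison enumerates ~100 deletion units per condition, a few
  hundred LP solves of roughly 110×160, which completes in seconds.

## Known limitations

No parsimonious/loopless FBA, no kinetics, no regulation (the myo-inositol
false positive stays a false positive by design), no more than two
compartments, no MIRIAM annotations, and reaction *removal* during curation
is manual (a curation table), since no algorithmic removal procedure is
defined for it. The ortholog map is consumed as a given one-to-one table;
sequence-based orthology detection is out of scope.
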