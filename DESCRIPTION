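Package: strainscope
Title: Constraint-Based Reconstruction Analysis and Comparison of
    Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the constraint-based analysis workflow used to refine
    and compare bacterial genome-scale metabolic models: flux balance
    analysis (FBA) with an in-silico growth medium, gene knockouts through
    gene-protein-reaction (GPR) boolean rules, mass- and charge-balance
    quality control, detection of thermodynamically infeasible
    energy-generating cycles, SMILEY-style minimal gap-filling against a
    reaction database, in-silico amino-acid requirement and carbohydrate
    utilization screens scored against observed phenotype tables, and
    CONGA-style differential gene-deletion comparison of two models with
    genetic/orthology/metabolic classification of each difference. Models
    are read and written as SBML (Level 3 + fbc, or SEED-era Level 2) or as
    plain tabular reaction lists. Includes deterministic generators for
    synthetic benchmark networks with planted auxotrophies, futile cycles,
    pathway gaps and paired-model differences, and synthetic stand-in
    models for two Lactobacillus casei strains. The linear and
    mixed-integer programs are solved by a built-in bounded-variable
    simplex and branch-and-bound core.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
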