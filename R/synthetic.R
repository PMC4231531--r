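# Deterministic generators for benchmark networks with planted, provable
# features: a core toy network (TOY-CORE), a futile ATP cycle, gap-filling
# scenarios with known minimal fills, and paired models with planted
# genetic / orthology / metabolic differences. Every generator returns a
# truth manifest sufficient to derive the expected output of the module it
# feeds.

#' TOY-CORE: a 12-metabolite, 14-reaction toy network
#'
#' Glucose uptake and a two-step glycolysis proxy generate ATP; biomass
#' consumes ATP plus two amino-acid precursors, one importable only
#' (`aan`, a planted auxotrophy) and one also synthesizable from pyruvate
#' (`aam`). On the default medium (10 mmol/gDW/h glucose and both amino
#' acids) the optimal growth rate has the closed form
#' `mu = min(glc_cap, 2 * aan_cap)`: one glucose yields 2 ATP and biomass
#' needs 2 ATP and 0.5 of each precursor per unit of growth.
#'
#' @param seed optional integer; when given, uptake capacities are drawn
#'   from feasibility-preserving ranges (glucose 6-12, amino acids 4-12
#'   mmol/gDW/h) so randomized variants still have a provable optimum.
#' @return list with `model`, `medium` and a truth `manifest`
#'   (`mu_full`, the planted auxotrophy and the synthesizable precursor).
#' @export
make_core_toy <- function(seed = NULL) {
  glc_cap <- 10; aan_cap <- 10; aam_cap <- 10
  if (!is.null(seed)) {
    set.seed(seed)
    glc_cap <- round(stats::runif(1, 6, 12), 3)
    aan_cap <- round(stats::runif(1, 4, 12), 3)
    aam_cap <- round(stats::runif(1, 4, 12), 3)
  }
  mets <- lapply(c("glc_e", "glc_c", "g6p_c", "pyr_c", "lac_c", "lac_e",
                   "atp_c", "adp_c", "aan_e", "aan_c", "aam_e", "aam_c"),
                 metabolite)
  rxns <- list(
    reaction("EX_glc", c(glc_e = -1), kind = "exchange", lb = 0, ub = 1000),
    reaction("GLCt", c(glc_e = -1, glc_c = 1), gpr = "gT"),
    reaction("HEX", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
             gpr = "g1"),
    reaction("GLY", c(g6p_c = -1, adp_c = -3, pyr_c = 2, atp_c = 3),
             gpr = "g2a or g2b"),
    reaction("LDH", c(pyr_c = -1, lac_c = 1), gpr = "g3"),
    reaction("LACt", c(lac_c = -1, lac_e = 1)),
    reaction("EX_lac", c(lac_e = -1), kind = "exchange", lb = 0, ub = 1000),
    reaction("EX_aan", c(aan_e = -1), kind = "exchange", lb = 0, ub = 1000),
    reaction("AANt", c(aan_e = -1, aan_c = 1), gpr = "g4"),
    reaction("EX_aam", c(aam_e = -1), kind = "exchange", lb = 0, ub = 1000),
    reaction("AAMt", c(aam_e = -1, aam_c = 1), gpr = "g5"),
    reaction("AAMS", c(pyr_c = -1, aam_c = 1), gpr = "g6 and g7"),
    reaction("ATPM", c(atp_c = -1, adp_c = 1)),
    reaction("BIOMASS", c(aan_c = -0.5, aam_c = -0.5, atp_c = -2, adp_c = 2),
             kind = "biomass")
  )
  model <- metabolic_model("TOY-CORE", mets, rxns, objective_id = "BIOMASS")
  medium <- medium_spec(EX_glc = glc_cap, EX_aan = aan_cap, EX_aam = aam_cap)
  manifest <- list(
    mu_full = min(glc_cap, 2 * aan_cap),
    auxotrophy = list(compound = "aan", exchange = "EX_aan"),
    synthesizable = list(compound = "aam", exchange = "EX_aam",
                         synthesis_reaction = "AAMS"),
    caps = c(glc = glc_cap, aan = aan_cap, aam = aam_cap)
  )
  list(model = model, medium = medium, manifest = manifest)
}

#' TOY-CORE with a planted ATP-generating futile cycle
#'
#' Adds a reversible pair whose net effect with all exchanges closed is
#' `adp -> atp` for free: `CYC_X: cycA + adp <-> cycB + atp` and
#' `CYC_Y: cycB <-> cycA`. With `repaired = TRUE` the second reaction is
#' restricted to the cycle-breaking direction (only `cycA -> cycB`
#' remains), which removes the infeasible cycle.
#'
#' @param repaired plant the cycle already repaired (default `FALSE`).
#' @return list with `model` and a truth `manifest` (`witness`: the cycle
#'   reactions, `repaired`).
#' @export
make_futile_cycle_model <- function(repaired = FALSE) {
  toy <- make_core_toy()
  model <- add_reactions(toy$model, list(
    reaction("CYC_X", c(cycA_c = -1, adp_c = -1, cycB_c = 1, atp_c = 1),
             reversible = TRUE),
    reaction("CYC_Y", c(cycB_c = -1, cycA_c = 1),
             lb = if (repaired) -1000 else -1000,
             ub = if (repaired) 0 else 1000)
  ))
  list(model = model, medium = toy$medium,
       manifest = list(witness = c("CYC_X", "CYC_Y"), repaired = repaired))
}

#' Gap-filling scenario with a known minimal fill
#'
#' Removes one or two reactions from a growing TOY-CORE so growth becomes
#' impossible, and assembles a candidate database containing the removed
#' reactions (unless withheld), a two-reaction bypass for the glycolysis
#' gap, and dead-end decoys that can never carry steady-state flux.
#'
#' @param n_gaps 1 (remove the glycolysis proxy `GLY`) or 2 (also remove
#'   the lactate drain `LDH`, which is needed as the pyruvate sink).
#' @param decoys number of dead-end decoy candidates (0-8).
#' @param withhold_truth drop the removed reactions *and* the bypass from
#'   the database, making the scenario unfillable.
#' @return list with `model` (gapped), `medium`, `database` (list of
#'   [reaction()] candidates) and a truth `manifest` (`removed`,
#'   `bypass`, `min_fill_size`).
#' @export
make_gap_scenario <- function(n_gaps = 1, decoys = 8, withhold_truth = FALSE) {
  stopifnot(n_gaps %in% c(1, 2), decoys >= 0, decoys <= 8)
  toy <- make_core_toy()
  removed <- if (n_gaps == 1) "GLY" else c("GLY", "LDH")
  truth <- lapply(removed, function(rid) {
    k <- rxn_index(toy$model, rid)
    reaction(rid, toy$model$stoich[[rid]], lb = toy$model$rxns$lb[k],
             ub = toy$model$rxns$ub[k])
  })
  model <- remove_reactions(toy$model, removed)
  bypass <- list(
    reaction("GLYB1", c(g6p_c = -1, adp_c = -3, bypx_c = 1, atp_c = 3)),
    reaction("GLYB2", c(bypx_c = -1, pyr_c = 2))
  )
  decoy_pool <- list(
    reaction("DK1", c(pyr_c = -1, dk1_c = 1)),
    reaction("DK2", c(glc_c = -1, dk2_c = 1)),
    reaction("DK3", c(aan_c = -1, dk3_c = 1)),
    reaction("DK4", c(lac_c = -1, dk4_c = 1), reversible = TRUE),
    reaction("DK5", c(g6p_c = -1, dk5_c = 1)),
    reaction("DK6", c(dk6a_c = -1, dk6b_c = 1), reversible = TRUE),
    reaction("DK7", c(aam_c = -1, dk7_c = 1)),
    reaction("DK8", c(adp_c = -1, dk8_c = 1))
  )
  db <- c(if (!withhold_truth) c(truth, bypass),
          decoy_pool[seq_len(decoys)])
  manifest <- list(
    removed = removed,
    bypass = if (n_gaps == 1 && !withhold_truth) c("GLYB1", "GLYB2") else character(0),
    min_fill_size = if (withhold_truth) NA_integer_ else n_gaps,
    fillable = !withhold_truth
  )
  list(model = model, medium = toy$medium, database = db, manifest = manifest)
}

#' Paired models with one planted functional difference
#'
#' Builds two TOY-CORE derivatives that differ in exactly one planted way,
#' mirroring the three explanations for a deletion set lethal in one model
#' only:
#'
#' * `"genetic"`: the essential lactate dehydrogenase carries GPR `g3` in
#'   model A but `g3 or g3b` in model B (an extra isozyme unique to B);
#'   deleting the `g3` ortholog pair is lethal only in A.
#' * `"orthology"`: the same reaction is gene-associated to `g3a` in A and
#'   `g3b` in B, but the pair is withheld from the ortholog map; each
#'   single deletion is lethal in its own model only.
#' * `"metabolic"`: biomass needs a cofactor made by a conversion step
#'   present in both models; both also carry a two-reaction detour that
#'   makes the cofactor while excreting a by-product, but only model B has
#'   the by-product export transporter (carrying no gene association), so
#'   only B survives deletion of the conversion step.
#' * `"none"`: identical models; no differential deletion set exists.
#'
#' @param category `"genetic"`, `"orthology"`, `"metabolic"` or `"none"`.
#' @return list with `model_a`, `model_b`, `orthologs` (data frame
#'   `gene_a`/`gene_b`), `medium` and a truth `manifest` (`expected_units`,
#'   `lethal_in`, `category`, `rescue`).
#' @export
make_paired_models <- function(category = c("genetic", "orthology",
                                            "metabolic", "none")) {
  category <- match.arg(category)
  toy <- make_core_toy()
  a <- toy$model; a$id <- "PAIR-A"
  b <- toy$model; b$id <- "PAIR-B"
  shared <- sort(a$genes)
  orth <- data.frame(gene_a = shared, gene_b = shared,
                     stringsAsFactors = FALSE)
  manifest <- list(category = category, expected_units = list(),
                   lethal_in = character(0), rescue = character(0))

  if (category == "genetic") {
    b$gpr[["LDH"]] <- parse_gpr("g3 or g3b")
    b$genes <- union(b$genes, "g3b")
    manifest$expected_units <- list(c(gene_a = "g3", gene_b = "g3"))
    manifest$lethal_in <- "A"
    manifest$rescue <- "LDH"
  } else if (category == "orthology") {
    a$gpr[["LDH"]] <- parse_gpr("g3a")
    a$genes <- union(setdiff(a$genes, "g3"), "g3a")
    b$gpr[["LDH"]] <- parse_gpr("g3b")
    b$genes <- union(setdiff(b$genes, "g3"), "g3b")
    orth <- orth[orth$gene_a != "g3", , drop = FALSE]
    manifest$expected_units <- list(c(gene_a = "g3a", gene_b = NA),
                                    c(gene_a = NA, gene_b = "g3b"))
    manifest$lethal_in <- c("A", "B")
    manifest$rescue <- "LDH"
  } else if (category == "metabolic") {
    motif <- list(
      reaction("CPS", c(pyr_c = -1, cpre_c = 1), gpr = "g9"),
      reaction("CONV", c(cpre_c = -1, cof_c = 1), gpr = "g8"),
      reaction("DET1", c(cpre_c = -1, cint_c = 1, byp_c = 1), gpr = "g10"),
      reaction("DET2", c(cint_c = -1, cof_c = 1), gpr = "g11")
    )
    a <- add_reactions(a, motif)
    b <- add_reactions(b, motif)
    b <- add_reactions(b, list(
      reaction("BYPt", c(byp_c = -1, byp_e = 1)),
      reaction("EX_byp", c(byp_e = -1), kind = "exchange", lb = 0, ub = 1000)
    ))
    ## biomass additionally requires the cofactor
    for (nm in c("a", "b")) {
      m <- get(nm)
      m$stoich[["BIOMASS"]]["cof_c"] <- -0.5
      assign(nm, m)
    }
    shared <- sort(union(a$genes, character(0)))
    orth <- data.frame(gene_a = shared, gene_b = shared,
                       stringsAsFactors = FALSE)
    ## the defining rescue element is the by-product exporter unique to B;
    ## the detour reactions exist in both models
    manifest$expected_units <- list(c(gene_a = "g8", gene_b = "g8"))
    manifest$lethal_in <- "A"
    manifest$rescue <- "BYPt"
  }
  list(model_a = a, model_b = b, orthologs = orth, medium = toy$medium,
       manifest = manifest)
}

#' Write a fixture bundle to disk
#'
#' Emits a generated fixture in both exchange formats (SBML Level 3 + fbc
#' and tabular TSV) together with its medium and truth manifest, so both
#' readers can be exercised on identical content.
#'
#' @param fixture a list as returned by the `make_*` generators (fields
#'   `model` or `model_a`/`model_b`, `medium`, `manifest`, optionally
#'   `database`, `orthologs`).
#' @param dir output directory (created if needed).
#' @return character vector of the files written.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit_model <- function(model, stem) {
    sb <- file.path(dir, paste0(stem, ".xml"))
    tsv <- file.path(dir, paste0(stem, ".tsv"))
    write_sbml(model, sb)
    write_model_tsv(model, tsv)
    c(sb, tsv)
  }
  if (!is.null(fixture$model)) {
    written <- c(written, emit_model(fixture$model, "model"))
  }
  if (!is.null(fixture$model_a)) {
    written <- c(written, emit_model(fixture$model_a, "model_a"),
                 emit_model(fixture$model_b, "model_b"))
  }
  if (!is.null(fixture$medium)) {
    mp <- file.path(dir, "medium.tsv")
    utils::write.table(
      data.frame(exchange_id = names(fixture$medium),
                 max_uptake = as.numeric(fixture$medium)),
      mp, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, mp)
  }
  if (!is.null(fixture$orthologs)) {
    op <- file.path(dir, "orthologs.tsv")
    utils::write.table(fixture$orthologs, op, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, op)
  }
  if (!is.null(fixture$database)) {
    dbp <- file.path(dir, "database.tsv")
    df <- data.frame(
      rxn_id = vapply(fixture$database, `[[`, character(1), "id"),
      equation = vapply(fixture$database, function(r) {
        format_equation(r$stoich, r$lb < 0)
      }, character(1)),
      lb = vapply(fixture$database, `[[`, numeric(1), "lb"),
      ub = vapply(fixture$database, `[[`, numeric(1), "ub"),
      gpr = vapply(fixture$database, function(r) gpr_to_string(r$gpr),
                   character(1)),
      kind = "metabolic", stringsAsFactors = FALSE)
    utils::write.table(df, dbp, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, dbp)
  }
  mfp <- file.path(dir, "manifest.json")
  jsonlite::write_json(fixture$manifest, mfp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  written <- c(written, mfp)
  invisible(written)
}
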