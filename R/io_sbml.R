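# SBML read/write.
#
# Writing targets SBML Level 3 Version 1 with the fbc version-2 package
# (flux bounds as global parameters, GPRs as geneProductAssociation trees,
# the biomass objective as the active fbc objective). Reading accepts that
# dialect plus SEED-era Level 2 exports, where flux bounds live in
# kineticLaw parameters named LOWER_BOUND/UPPER_BOUND and GPRs in reaction
# notes lines such as "GENE_ASSOCIATION: (g1 and g2) or g3". Every fallback
# taken on a Level 2 file is counted and reported once via message().

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xfind <- function(node, local) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", local))
}
xfind1 <- function(node, local) {
  xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", local))
}
xchild <- function(node, local) {
  xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", local))
}

sanitize_sid <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("x_", x))
}

#' Write a model as SBML Level 3 + fbc
#'
#' @param model a `metabolic_model`.
#' @param path output file path, or `NULL` to return the document as a
#'   character string.
#' @return `path` invisibly, or the SBML text when `path` is `NULL`.
#' @export
write_sbml <- function(model, path = NULL) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model$id),
                               name = model$id, "fbc:strict" = "false")

  loc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in COMPARTMENTS) {
    xml2::xml_add_child(loc, "compartment", id = cp, name = cp,
                        constant = "true")
  }

  los <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    sp <- xml2::xml_add_child(
      los, "species", id = sanitize_sid(model$mets$id[i]),
      name = model$mets$name[i], compartment = model$mets$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(model$mets$charge[i])) {
      xml2::xml_set_attr(sp, "fbc:charge", as.character(model$mets$charge[i]))
    }
    if (!is.na(model$mets$formula[i])) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", model$mets$formula[i])
    }
  }

  bound_vals <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bound_ids <- stats::setNames(sprintf("fb_%d", seq_along(bound_vals)),
                               format(bound_vals, digits = 15, trim = TRUE))
  lop <- xml2::xml_add_child(mnode, "listOfParameters")
  for (i in seq_along(bound_vals)) {
    xml2::xml_add_child(lop, "parameter", id = sprintf("fb_%d", i),
                        value = format(bound_vals[i], digits = 15, trim = TRUE),
                        constant = "true")
  }
  bid <- function(v) bound_ids[[format(v, digits = 15, trim = TRUE)]]

  write_gpr_node <- function(parent, node) {
    if (node$op == "gene") {
      ref <- xml2::xml_add_child(parent, "fbc:geneProductRef")
      xml2::xml_set_attr(ref, "fbc:geneProduct",
                         paste0("gp_", sanitize_sid(node$gene)))
      return(invisible(NULL))
    }
    inner <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    for (a in node$args) write_gpr_node(inner, a)
    invisible(NULL)
  }

  lor <- xml2::xml_add_child(mnode, "listOfReactions")
  for (i in seq_len(nrow(model$rxns))) {
    rid <- model$rxns$id[i]
    rn <- xml2::xml_add_child(
      lor, "reaction", id = sanitize_sid(rid), name = model$rxns$name[i],
      reversible = if (model$rxns$lb[i] < 0) "true" else "false",
      fast = "false")
    xml2::xml_set_attr(rn, "fbc:lowerFluxBound", bid(model$rxns$lb[i]))
    xml2::xml_set_attr(rn, "fbc:upperFluxBound", bid(model$rxns$ub[i]))
    st <- model$stoich[[rid]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs) > 0L) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (mid in names(subs)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = sanitize_sid(mid),
                            stoichiometry = format(-subs[[mid]], digits = 15),
                            constant = "true")
      }
    }
    if (length(prods) > 0L) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (mid in names(prods)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = sanitize_sid(mid),
                            stoichiometry = format(prods[[mid]], digits = 15),
                            constant = "true")
      }
    }
    g <- model$gpr[[rid]]
    if (!is.null(g)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      write_gpr_node(gpa, unclass(g))
    }
  }

  if (!is.na(model$objective_id)) {
    loo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives")
    xml2::xml_set_attr(loo, "fbc:activeObjective", "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective")
    xml2::xml_set_attr(ob, "fbc:id", "obj")
    xml2::xml_set_attr(ob, "fbc:type", "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    fo <- xml2::xml_add_child(lfo, "fbc:fluxObjective")
    xml2::xml_set_attr(fo, "fbc:reaction", sanitize_sid(model$objective_id))
    xml2::xml_set_attr(fo, "fbc:coefficient", "1")
  }

  if (length(model$genes) > 0L) {
    lgp <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      gp <- xml2::xml_add_child(lgp, "fbc:geneProduct")
      xml2::xml_set_attr(gp, "fbc:id", paste0("gp_", sanitize_sid(g)))
      xml2::xml_set_attr(gp, "fbc:label", g)
    }
  }

  if (is.null(path)) {
    return(as.character(doc))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML
#'
#' Accepts Level 3 + fbc documents and SEED-era Level 2 documents (bounds
#' from kineticLaw parameters, GPRs from notes). Reaction kinds are
#' classified on read: exchange = touches exactly one extracellular
#' species; biomass = the detected objective; sink = any other
#' single-species reaction; everything else metabolic. Boundary-condition
#' species are dropped from the stoichiometry.
#'
#' Objective detection order: active fbc objective, then a reaction whose
#' id or name contains "biomass" (case-insensitive), then an explicit
#' "no objective" error.
#'
#' @param x a file path or a literal SBML string (anything starting
#'   with `<`).
#' @param require_objective error when no biomass objective can be
#'   detected (default `TRUE`).
#' @param id optional model id override.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(x, require_objective = TRUE, id = NULL) {
  doc <- tryCatch(
    if (grepl("^[[:space:]]*<", x)) xml2::read_xml(x) else xml2::read_xml(x),
    error = function(e) {
      stop("SBML parse error: ", conditionMessage(e), call. = FALSE)
    })
  root <- xml2::xml_root(doc)
  level <- suppressWarnings(as.integer(xml2::xml_attr(root, "level")))
  if (is.na(level)) level <- 3L
  mnode <- xfind1(doc, "model")
  if (is.na(xml2::xml_name(mnode))) stop("SBML parse error: no <model> element")
  model_id <- if (!is.null(id)) id else {
    mid <- xml2::xml_attr(mnode, "id")
    if (is.na(mid)) "sbml_model" else mid
  }
  fallbacks <- 0L

  ## compartments: anything whose id/name mentions "extra" or is e/e0 is
  ## extracellular, the rest cytoplasm
  comp_map <- character(0)
  for (cn in xchild(xfind1(mnode, "listOfCompartments"), "compartment")) {
    cid <- xml2::xml_attr(cn, "id")
    lab <- tolower(paste(cid, xml2::xml_attr(cn, "name")))
    comp_map[cid] <- if (grepl("extra", lab) || cid %in% c("e", "e0", "Extracellular")) {
      "extracellular"
    } else {
      "cytoplasm"
    }
  }

  notes_field <- function(node, keys) {
    nn <- xfind1(node, "notes")
    if (is.na(xml2::xml_name(nn))) return(NA_character_)
    ps <- xfind(nn, "p")
    lines <- if (length(ps) > 0L) {
      vapply(ps, xml2::xml_text, character(1))
    } else {
      strsplit(xml2::xml_text(nn), "\n", fixed = TRUE)[[1L]]
    }
    for (key in keys) {
      hit <- grep(paste0("^\\s*", key, "\\s*:"), lines)
      if (length(hit) > 0L) {
        val <- trimws(sub(paste0("^\\s*", key, "\\s*:\\s*"), "",
                          lines[hit[1L]]))
        if (nzchar(val)) return(val)
      }
    }
    NA_character_
  }

  mets <- list()
  boundary <- character(0)
  for (sn in xchild(xfind1(mnode, "listOfSpecies"), "species")) {
    sid <- xml2::xml_attr(sn, "id")
    if (identical(xml2::xml_attr(sn, "boundaryCondition"), "true")) {
      boundary <- c(boundary, sid)
      next
    }
    cid <- xml2::xml_attr(sn, "compartment")
    comp <- if (!is.na(cid) && cid %in% names(comp_map)) {
      comp_map[[cid]]
    } else {
      infer_compartment(sid)
    }
    formula <- xml2::xml_attr(sn, "chemicalFormula")
    if (is.na(formula)) formula <- notes_field(sn, "FORMULA")
    charge <- xml2::xml_attr(sn, "charge")
    if (is.na(charge)) charge <- notes_field(sn, "CHARGE")
    nm <- xml2::xml_attr(sn, "name")
    mets[[length(mets) + 1L]] <- metabolite(
      sid, name = if (is.na(nm)) sid else nm, compartment = comp,
      formula = formula,
      charge = suppressWarnings(as.integer(charge)))
  }
  met_ids <- vapply(mets, `[[`, character(1), "id")

  ## flux-bound parameters (L3) and gene products (fbc)
  params <- numeric(0)
  lop <- xml2::xml_find_first(mnode, "./*[local-name()='listOfParameters']")
  if (!is.na(xml2::xml_name(lop))) {
    for (pn in xchild(lop, "parameter")) {
      params[xml2::xml_attr(pn, "id")] <-
        suppressWarnings(as.numeric(xml2::xml_attr(pn, "value")))
    }
  }
  gp_label <- character(0)
  for (gp in xfind(mnode, "geneProduct")) {
    gid <- xml2::xml_attr(gp, "id")
    lab <- xml2::xml_attr(gp, "label")
    gp_label[gid] <- if (is.na(lab)) gid else lab
  }

  read_gpr_node <- function(node) {
    ln <- xml2::xml_name(node)
    if (ln == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      gene <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
      return(list(op = "gene", gene = gene))
    }
    if (ln %in% c("and", "or")) {
      kids <- xml2::xml_children(node)
      return(list(op = ln, args = lapply(kids, read_gpr_node)))
    }
    stop("SBML parse error: unexpected node in geneProductAssociation: ", ln)
  }

  rxns <- list()
  for (rn in xchild(xfind1(mnode, "listOfReactions"), "reaction")) {
    rid <- xml2::xml_attr(rn, "id")
    nm <- xml2::xml_attr(rn, "name")
    rev_attr <- xml2::xml_attr(rn, "reversible")
    reversible <- is.na(rev_attr) || rev_attr == "true"   # L2 default: true

    st <- numeric(0)
    lre <- xml2::xml_find_first(rn, "./*[local-name()='listOfReactants']")
    if (!is.na(xml2::xml_name(lre))) {
      for (sr in xchild(lre, "speciesReference")) {
        coef <- xml2::xml_attr(sr, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        mid <- xml2::xml_attr(sr, "species")
        st[mid] <- ifelse(is.na(st[mid]), 0, st[mid]) - coef
      }
    }
    lpr <- xml2::xml_find_first(rn, "./*[local-name()='listOfProducts']")
    if (!is.na(xml2::xml_name(lpr))) {
      for (sr in xchild(lpr, "speciesReference")) {
        coef <- xml2::xml_attr(sr, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        mid <- xml2::xml_attr(sr, "species")
        st[mid] <- ifelse(is.na(st[mid]), 0, st[mid]) + coef
      }
    }
    st <- st[!(names(st) %in% boundary)]
    st <- st[st != 0]

    ## bounds: fbc parameters, else kineticLaw (L2), else defaults
    lb <- NA_real_; ub <- NA_real_
    lbid <- xml2::xml_attr(rn, "lowerFluxBound")
    ubid <- xml2::xml_attr(rn, "upperFluxBound")
    if (!is.na(lbid) && lbid %in% names(params)) lb <- params[[lbid]]
    if (!is.na(ubid) && ubid %in% names(params)) ub <- params[[ubid]]
    if (is.na(lb) || is.na(ub)) {
      kl <- xml2::xml_find_first(rn, "./*[local-name()='kineticLaw']")
      if (!is.na(xml2::xml_name(kl))) {
        for (pn in xfind(kl, "parameter")) {
          pid <- xml2::xml_attr(pn, "id")
          pnm <- xml2::xml_attr(pn, "name")
          key <- toupper(ifelse(is.na(pid), pnm, pid))
          val <- suppressWarnings(as.numeric(xml2::xml_attr(pn, "value")))
          if (identical(key, "LOWER_BOUND") && is.na(lb)) lb <- val
          if (identical(key, "UPPER_BOUND") && is.na(ub)) ub <- val
        }
        if (!is.na(lb) || !is.na(ub)) fallbacks <- fallbacks + 1L
      }
    }
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000

    ## GPR: fbc association, else notes (L2)
    gpr <- NULL
    gpa <- xml2::xml_find_first(
      rn, "./*[local-name()='geneProductAssociation']")
    if (!is.na(xml2::xml_name(gpa))) {
      kids <- xml2::xml_children(gpa)
      if (length(kids) > 0L) {
        gpr <- structure(read_gpr_node(kids[[1L]]), class = "gpr")
      }
    } else {
      ga <- notes_field(rn, c("GENE_ASSOCIATION", "GENE ASSOCIATION", "GPR"))
      if (!is.na(ga) && nzchar(ga)) {
        gpr <- parse_gpr(ga)
        fallbacks <- fallbacks + 1L
      }
    }

    rxns[[length(rxns) + 1L]] <- list(id = rid, name = if (is.na(nm)) rid else nm,
                                      stoich = st, lb = lb, ub = ub, gpr = gpr)
  }

  ## objective detection: fbc active objective -> name match -> error
  objective <- NA_character_
  fo <- xfind1(mnode, "fluxObjective")
  if (!is.na(xml2::xml_name(fo))) {
    objective <- xml2::xml_attr(fo, "reaction")
  }
  rxn_ids <- vapply(rxns, `[[`, character(1), "id")
  rxn_names <- vapply(rxns, `[[`, character(1), "name")
  if (is.na(objective)) {
    hit <- which(grepl("biomass", rxn_ids, ignore.case = TRUE) |
                   grepl("biomass", rxn_names, ignore.case = TRUE))
    if (length(hit) > 0L) objective <- rxn_ids[hit[1L]]
  }
  if (is.na(objective) && require_objective) {
    stop(sprintf("no objective: model '%s' has no detectable biomass reaction",
                 model_id))
  }

  comp_of <- stats::setNames(vapply(mets, `[[`, character(1), "compartment"),
                             met_ids)
  rx_objs <- lapply(rxns, function(r) {
    kind <- "metabolic"
    if (length(r$stoich) == 1L) {
      kind <- if (comp_of[[names(r$stoich)]] == "extracellular") "exchange" else "sink"
    }
    if (!is.na(objective) && r$id == objective) kind <- "biomass"
    reaction(r$id, r$stoich, name = r$name, lb = r$lb, ub = r$ub,
             gpr = r$gpr, kind = kind)
  })

  genes <- unique(c(unname(gp_label),
                    unlist(lapply(rx_objs, function(r) gpr_genes(r$gpr)),
                           use.names = FALSE)))
  if (fallbacks > 0L) {
    message(sprintf("read_sbml: used %d Level-2 fallback(s) (kineticLaw bounds / notes GPRs)",
                    fallbacks))
  }
  metabolic_model(model_id, mets, rx_objs, genes = genes,
                  objective_id = objective)
}
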