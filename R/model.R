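# Domain types: metabolites, reactions, metabolic models, stoichiometric
# matrices, and the component-count summary.
#
# A model holds two compartments (cytoplasm, extracellular). Exchange
# reactions are single-metabolite boundary drains on extracellular species
# with the convention negative flux = uptake, positive = secretion; sink
# reactions are single-metabolite intracellular drains; the biomass
# pseudo-reaction is the growth objective and its flux is the growth rate
# in 1/h. All other bounds are in mmol/gDW/h.

COMPARTMENTS <- c("cytoplasm", "extracellular")

#' Create a metabolite
#'
#' @param id unique metabolite id. When `compartment` is missing it is
#'   inferred from the id suffix: `_e`, `[e]` or `[e0]` mean extracellular,
#'   anything else (conventionally `_c`, `[c]`, `[c0]`) cytoplasm.
#' @param name display name (defaults to the id).
#' @param compartment `"cytoplasm"` or `"extracellular"`.
#' @param formula elemental formula in Hill notation (e.g. `"C6H12O6"`), or
#'   `NA` when unknown.
#' @param charge integer formal charge, or `NA`.
#' @return a list of class `metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = infer_compartment(id),
                       formula = NA_character_, charge = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  compartment <- match.arg(compartment, COMPARTMENTS)
  structure(list(id = id, name = name, compartment = compartment,
                 formula = as.character(formula),
                 charge = as.integer(charge)),
            class = "metabolite")
}

#' Infer a compartment from a metabolite id suffix
#'
#' Recognizes the `_e` convention and the SEED-style `[e]` / `[e0]`
#' suffixes as extracellular; everything else is cytoplasm.
#'
#' @param id metabolite id.
#' @return `"extracellular"` or `"cytoplasm"`.
#' @export
infer_compartment <- function(id) {
  if (grepl("(_e$)|(\\[e0?\\]$)", id)) "extracellular" else "cytoplasm"
}

#' Create a reaction
#'
#' @param id unique reaction id.
#' @param stoich named numeric vector of stoichiometric coefficients by
#'   metabolite id; negative = consumed, positive = produced.
#' @param name display name.
#' @param lb,ub flux bounds (mmol/gDW/h; 1/h for biomass). Defaults follow
#'   the COBRA convention: `(-1000, 1000)` if `reversible`, else `(0, 1000)`.
#' @param gpr GPR rule as a string (see [parse_gpr()]), a `gpr` object, or
#'   `NULL`/`""` for no gene association.
#' @param kind one of `"metabolic"`, `"exchange"`, `"biomass"`, `"sink"`.
#' @param reversible used only to pick default bounds when `lb`/`ub` are
#'   missing.
#' @param ec_numbers optional character vector of EC numbers.
#' @return a list of class `reaction`.
#' @export
reaction <- function(id, stoich, name = id, lb = NULL, ub = NULL, gpr = NULL,
                     kind = c("metabolic", "exchange", "biomass", "sink"),
                     reversible = FALSE, ec_numbers = character(0)) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(names(stoich)) && length(stoich) > 0L) {
    stop("stoich must be a named numeric vector (metabolite id -> coefficient)")
  }
  stoich <- stoich[stoich != 0]
  if (is.null(lb)) lb <- if (reversible) -1000 else 0
  if (is.null(ub)) ub <- 1000
  if (lb > ub) stop(sprintf("reaction '%s': lower bound exceeds upper bound", id))
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = as_gpr(gpr), kind = kind,
                 ec_numbers = as.character(ec_numbers)),
            class = "reaction")
}

#' Assemble a genome-scale metabolic model
#'
#' @param id model id.
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param genes character vector of gene ids; when `NULL`, the union of all
#'   GPR genes is used. Every GPR leaf must be in the gene list.
#' @param objective_id id of the biomass reaction, or `NA` for a model
#'   without an objective (FBA will refuse to run on it).
#' @return a list of class `metabolic_model` with elements `id`, `genes`,
#'   `mets` (data frame), `rxns` (data frame), `stoich` (list of named
#'   numeric vectors by reaction id), `gpr` (list by reaction id) and
#'   `objective_id`.
#' @export
metabolic_model <- function(id, metabolites, reactions, genes = NULL,
                            objective_id = NA_character_) {
  mets <- data.frame(
    id = vapply(metabolites, `[[`, character(1), "id"),
    name = vapply(metabolites, `[[`, character(1), "name"),
    compartment = vapply(metabolites, `[[`, character(1), "compartment"),
    formula = vapply(metabolites, function(m) as.character(m$formula)[1], character(1)),
    charge = vapply(metabolites, function(m) as.integer(m$charge)[1], integer(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  rxns <- data.frame(
    id = rids,
    name = vapply(reactions, `[[`, character(1), "name"),
    lb = vapply(reactions, `[[`, numeric(1), "lb"),
    ub = vapply(reactions, `[[`, numeric(1), "ub"),
    kind = vapply(reactions, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE
  )
  stoich <- lapply(reactions, `[[`, "stoich")
  names(stoich) <- rids
  gpr <- lapply(reactions, `[[`, "gpr")
  names(gpr) <- rids
  ec <- lapply(reactions, `[[`, "ec_numbers")
  names(ec) <- rids

  gpr_gene_ids <- unique(unlist(lapply(gpr, gpr_genes), use.names = FALSE))
  if (is.null(genes)) genes <- gpr_gene_ids
  genes <- unique(as.character(genes))
  missing_genes <- setdiff(gpr_gene_ids, genes)
  if (length(missing_genes) > 0L) {
    stop("GPR references genes absent from the gene list: ",
         paste(missing_genes, collapse = ", "))
  }

  model <- structure(
    list(id = id, genes = genes, mets = mets, rxns = rxns,
         stoich = stoich, gpr = gpr, ec = ec,
         objective_id = objective_id),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks that stoichiometry keys resolve to metabolites, bounds are
#' ordered, exchange reactions touch exactly one extracellular metabolite,
#' sinks touch exactly one metabolite, and the objective (when set)
#' resolves to a biomass reaction.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- model$mets$id
  for (rid in model$rxns$id) {
    st <- model$stoich[[rid]]
    unknown <- setdiff(names(st), met_ids)
    if (length(unknown) > 0L) {
      stop(sprintf("reaction '%s' references unknown metabolites: %s",
                   rid, paste(unknown, collapse = ", ")))
    }
  }
  if (any(model$rxns$lb > model$rxns$ub)) {
    bad <- model$rxns$id[model$rxns$lb > model$rxns$ub][1]
    stop(sprintf("reaction '%s': lower bound exceeds upper bound", bad))
  }
  comp <- stats::setNames(model$mets$compartment, model$mets$id)
  for (rid in model$rxns$id[model$rxns$kind == "exchange"]) {
    st <- model$stoich[[rid]]
    if (length(st) != 1L || comp[[names(st)]] != "extracellular") {
      stop(sprintf(
        "exchange reaction '%s' must touch exactly one extracellular metabolite",
        rid))
    }
  }
  for (rid in model$rxns$id[model$rxns$kind == "sink"]) {
    if (length(model$stoich[[rid]]) != 1L) {
      stop(sprintf("sink reaction '%s' must touch exactly one metabolite", rid))
    }
  }
  if (!is.na(model$objective_id)) {
    k <- match(model$objective_id, model$rxns$id)
    if (is.na(k)) {
      stop(sprintf("objective reaction '%s' not in model", model$objective_id))
    }
    if (model$rxns$kind[k] != "biomass") {
      stop(sprintf("objective reaction '%s' is not of kind 'biomass'",
                   model$objective_id))
    }
  }
  invisible(model)
}

#' Build the sparse stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return a [Matrix::sparseMatrix()] `S` of dimension
#'   (metabolites x reactions) with dimnames set to the ids; `S[i, j]` is
#'   the coefficient of metabolite i in reaction j.
#' @export
build_stoich_matrix <- function(model) {
  met_ids <- model$mets$id
  rxn_ids <- model$rxns$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    st <- model$stoich[[rxn_ids[j]]]
    if (length(st) == 0L) next
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Component counts of a model
#'
#' Tabulates genes, metabolites (total / intracellular / extracellular) and
#' reactions (total / exchange / metabolic / non-metabolic, and metabolic
#' reactions with / without a GPR), in the layout customary for
#' model-overview tables.
#'
#' @param model a `metabolic_model`.
#' @return a list of class `component_counts`.
#' @export
model_summary <- function(model) {
  is_metabolic <- model$rxns$kind == "metabolic"
  has_gpr <- !vapply(model$rxns$id, function(rid) is.null(model$gpr[[rid]]),
                     logical(1))
  counts <- list(
    model_id = model$id,
    genes = length(model$genes),
    metabolites = nrow(model$mets),
    metabolites_intracellular = sum(model$mets$compartment == "cytoplasm"),
    metabolites_extracellular = sum(model$mets$compartment == "extracellular"),
    reactions = nrow(model$rxns),
    reactions_exchange = sum(model$rxns$kind == "exchange"),
    reactions_metabolic = sum(is_metabolic),
    reactions_non_metabolic = sum(model$rxns$kind %in% c("biomass", "sink")),
    metabolic_with_gpr = sum(is_metabolic & has_gpr),
    metabolic_without_gpr = sum(is_metabolic & !has_gpr)
  )
  structure(counts, class = "component_counts")
}

#' @export
print.component_counts <- function(x, ...) {
  cat(sprintf("Model %s\n", x$model_id))
  cat(sprintf("  genes        %d\n", x$genes))
  cat(sprintf("  metabolites  %d (%d intracellular, %d extracellular)\n",
              x$metabolites, x$metabolites_intracellular,
              x$metabolites_extracellular))
  cat(sprintf("  reactions    %d (%d exchange, %d metabolic, %d non-metabolic)\n",
              x$reactions, x$reactions_exchange, x$reactions_metabolic,
              x$reactions_non_metabolic))
  cat(sprintf("  metabolic with GPR %d, without GPR %d\n",
              x$metabolic_with_gpr, x$metabolic_without_gpr))
  invisible(x)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$mets), nrow(x$rxns), length(x$genes)))
  if (!is.na(x$objective_id)) {
    cat(sprintf("  objective: %s\n", x$objective_id))
  }
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) model_summary(object)

## --- small internal accessors -------------------------------------------

rxn_index <- function(model, rid) {
  k <- match(rid, model$rxns$id)
  if (anyNA(k)) {
    stop("unknown reaction id(s): ", paste(rid[is.na(k)], collapse = ", "))
  }
  k
}

exchange_ids <- function(model) model$rxns$id[model$rxns$kind == "exchange"]

set_bounds <- function(model, rid, lb = NULL, ub = NULL) {
  k <- rxn_index(model, rid)
  if (!is.null(lb)) model$rxns$lb[k] <- lb
  if (!is.null(ub)) model$rxns$ub[k] <- ub
  model
}

#' Add reactions (and any new metabolites) to a model
#'
#' New metabolites referenced by the added reactions are created with
#' compartments inferred from their id suffixes and unknown formulas.
#'
#' @param model a `metabolic_model`.
#' @param reactions list of [reaction()] objects with ids not already in
#'   the model.
#' @return the extended, revalidated model.
#' @export
add_reactions <- function(model, reactions) {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  for (rx in reactions) {
    if (rx$id %in% model$rxns$id) {
      stop(sprintf("reaction '%s' already in model", rx$id))
    }
    new_mets <- setdiff(names(rx$stoich), model$mets$id)
    for (mid in new_mets) {
      model$mets <- rbind(model$mets, data.frame(
        id = mid, name = mid, compartment = infer_compartment(mid),
        formula = NA_character_, charge = NA_integer_,
        stringsAsFactors = FALSE))
    }
    model$rxns <- rbind(model$rxns, data.frame(
      id = rx$id, name = rx$name, lb = rx$lb, ub = rx$ub, kind = rx$kind,
      stringsAsFactors = FALSE))
    model$stoich[[rx$id]] <- rx$stoich
    ## single-bracket list assignment so a NULL GPR is stored, not dropped
    model$gpr[rx$id] <- list(rx$gpr)
    model$ec[rx$id] <- list(rx$ec_numbers)
    model$genes <- union(model$genes, gpr_genes(rx$gpr))
  }
  validate_model(model)
  model
}

#' Remove reactions from a model
#'
#' @param model a `metabolic_model`.
#' @param rids reaction ids to drop.
#' @return the reduced model (metabolites are kept even if orphaned).
#' @export
remove_reactions <- function(model, rids) {
  k <- rxn_index(model, rids)
  model$rxns <- model$rxns[-k, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$stoich[rids] <- NULL
  model$gpr[rids] <- NULL
  model$ec[rids] <- NULL
  if (!is.na(model$objective_id) && model$objective_id %in% rids) {
    model$objective_id <- NA_character_
  }
  model
}
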