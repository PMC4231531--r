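# Differential gene-deletion comparison of two models (CONGA-style):
# enumerate deletion sets over ortholog pairs and unique genes, keep the
# minimal sets lethal in exactly one model, and classify each difference
# as genetic (GPR/isozyme), orthology (equivalent genes not mapped) or
# metabolic (reactions unique to one network).

#' Single-gene deletion scan
#'
#' Deletes each gene in turn and records the resulting maximum growth
#' rate. Genes that appear in no GPR are reported at the baseline growth
#' rate without re-solving.
#'
#' @param model a `metabolic_model`.
#' @param medium growth condition (baseline must grow).
#' @param genes genes to scan (default: all model genes).
#' @param eps growth threshold.
#' @return named numeric vector of growth rates (infeasible deletions
#'   report 0).
#' @export
single_deletion_scan <- function(model, medium, genes = model$genes,
                                 eps = growth_eps()) {
  m0 <- apply_medium(model, medium)
  base <- solve_fba(m0)
  if (!grows(base, eps)) {
    stop(sprintf("model '%s' does not grow on the given medium", model$id))
  }
  in_gpr <- unique(unlist(lapply(model$gpr, gpr_genes), use.names = FALSE))
  vapply(genes, function(g) {
    if (!(g %in% in_gpr)) return(base$objective_value)
    sol <- solve_fba(knock_out(m0, g))
    if (sol$status == "optimal") sol$objective_value else 0
  }, numeric(1))
}

## deletion units: ortholog pairs (joint deletion) and unique genes,
## restricted to genes that appear in at least one GPR of their model
deletion_units <- function(model_a, model_b, orthologs) {
  gpr_a <- unique(unlist(lapply(model_a$gpr, gpr_genes), use.names = FALSE))
  gpr_b <- unique(unlist(lapply(model_b$gpr, gpr_genes), use.names = FALSE))
  bad <- setdiff(c(orthologs$gene_a), model_a$genes)
  bad <- c(bad, setdiff(c(orthologs$gene_b), model_b$genes))
  if (length(bad) > 0L) {
    stop("ortholog map references unknown genes: ",
         paste(unique(bad), collapse = ", "))
  }
  if (anyDuplicated(orthologs$gene_a) || anyDuplicated(orthologs$gene_b)) {
    stop("ortholog map is not one-to-one")
  }
  units <- list()
  for (i in seq_len(nrow(orthologs))) {
    ga <- orthologs$gene_a[i]; gb <- orthologs$gene_b[i]
    if (ga %in% gpr_a || gb %in% gpr_b) {
      units[[length(units) + 1L]] <- list(
        label = paste0(ga, "~", gb), genes_a = ga, genes_b = gb,
        type = "pair")
    }
  }
  for (g in setdiff(intersect(model_a$genes, gpr_a), orthologs$gene_a)) {
    units[[length(units) + 1L]] <- list(label = g, genes_a = g,
                                        genes_b = character(0),
                                        type = "unique_a")
  }
  for (g in setdiff(intersect(model_b$genes, gpr_b), orthologs$gene_b)) {
    units[[length(units) + 1L]] <- list(label = g, genes_a = character(0),
                                        genes_b = g, type = "unique_b")
  }
  units
}

#' Compare two models by differential gene deletions
#'
#' Enumerates deletion sets of up to `max_set_size` deletion units - a
#' unit is either an ortholog pair (both genes deleted jointly, one in
#' each model) or a gene unique to one model - and reports the minimal
#' sets lethal in exactly one model, each classified by
#' [classify_difference()]. Supersets of reported sets are pruned, so
#' every reported set is minimal.
#'
#' @param model_a,model_b `metabolic_model`s.
#' @param orthologs data frame with columns `gene_a`, `gene_b` (one-to-one).
#' @param medium shared growth condition (both models must grow on it).
#' @param max_set_size maximum number of units deleted together.
#' @param eps growth threshold.
#' @return list of class `model_comparison`; element `sets` is a list of
#'   differential deletion sets with fields `units`, `genes_a`, `genes_b`,
#'   `mu_a`, `mu_b`, `lethal_in` ("A" or "B"), `category`, `rescue`
#'   (reaction ids active in the surviving model that explain the rescue).
#' @export
compare_models <- function(model_a, model_b, orthologs, medium,
                           max_set_size = 2L, eps = growth_eps()) {
  ma <- apply_medium(model_a, medium_restrict(medium, model_a))
  mb <- apply_medium(model_b, medium_restrict(medium, model_b))
  base_a <- solve_fba(ma)
  base_b <- solve_fba(mb)
  if (!grows(base_a, eps) || !grows(base_b, eps)) {
    stop("both models must grow on the shared medium before comparison")
  }
  units <- deletion_units(model_a, model_b, orthologs)
  nu <- length(units)
  found <- list()
  found_idx <- list()

  mu_after <- function(m, genes) {
    if (length(genes) == 0L) return(Inf)   # deletion does not touch this model
    sol <- solve_fba(knock_out(m, genes))
    if (sol$status == "optimal") sol$objective_value else 0
  }

  eval_set <- function(idx) {
    ga <- unlist(lapply(units[idx], `[[`, "genes_a"), use.names = FALSE)
    gb <- unlist(lapply(units[idx], `[[`, "genes_b"), use.names = FALSE)
    mu_a <- if (length(ga) > 0L) mu_after(ma, ga) else base_a$objective_value
    mu_b <- if (length(gb) > 0L) mu_after(mb, gb) else base_b$objective_value
    list(mu_a = mu_a, mu_b = mu_b, genes_a = ga, genes_b = gb)
  }

  for (size in seq_len(max_set_size)) {
    combos <- utils::combn(nu, size, simplify = FALSE)
    for (idx in combos) {
      ## prune supersets of already-found differential sets
      if (any(vapply(found_idx, function(f) all(f %in% idx), logical(1)))) next
      ev <- eval_set(idx)
      dead_a <- ev$mu_a < eps
      dead_b <- ev$mu_b < eps
      if (dead_a == dead_b) next
      lethal_in <- if (dead_a) "A" else "B"
      det <- classify_difference(
        list(genes_a = ev$genes_a, genes_b = ev$genes_b,
             lethal_in = lethal_in),
        model_a = ma, model_b = mb, orthologs = orthologs, eps = eps)
      found[[length(found) + 1L]] <- list(
        units = vapply(units[idx], `[[`, character(1), "label"),
        genes_a = ev$genes_a, genes_b = ev$genes_b,
        mu_a = ev$mu_a, mu_b = ev$mu_b, lethal_in = lethal_in,
        category = det$category, rescue = det$rescue,
        low_confidence = det$low_confidence)
      found_idx[[length(found_idx) + 1L]] <- idx
    }
  }
  structure(list(sets = found, model_a = model_a$id, model_b = model_b$id,
                 n_units = nu, max_set_size = max_set_size),
            class = "model_comparison")
}

## restrict a medium to the exchanges a model actually has (paired models
## may differ in their exchange sets, e.g. a secretion unique to one)
medium_restrict <- function(medium, model) {
  if (!inherits(medium, "medium_spec")) medium <- medium_spec(medium)
  keep <- names(medium) %in% exchange_ids(model)
  medium_spec(stats::setNames(as.numeric(medium)[keep], names(medium)[keep]))
}

#' Classify a differential deletion set
#'
#' Decision procedure, evaluated in this order on the reactions disabled
#' by the deletion in the lethal model:
#'
#' 1. **genetic** - every disabled reaction has a same-id counterpart in
#'    the survivor whose GPR still evaluates true (an extra isozyme), and
#'    at least one rescuing gene is a genuine isozyme difference rather
#'    than an unmapped equal-function gene;
#' 2. **orthology** - every disabled reaction is rescued by a same-id
#'    counterpart, and the rescuing genes are unmapped genes whose
#'    equal-function partner (also unmapped) was deleted in the lethal
#'    model;
#' 3. **metabolic** - some disabled reaction has no surviving counterpart;
#'    the survivor reroutes through reactions the lethal model lacks. The
#'    rescue route reports the survivor's active reactions that are absent
#'    from the lethal model or replace its disabled ones. When no such
#'    unique reaction is active the set is still labelled metabolic but
#'    flagged low-confidence.
#'
#' @param set list with `genes_a`, `genes_b`, `lethal_in` ("A"/"B").
#' @param model_a,model_b the compared models (with the medium applied).
#' @param orthologs the ortholog map used for the comparison.
#' @param eps growth threshold.
#' @return list with `category`, `rescue` (reaction ids), `low_confidence`.
#' @export
classify_difference <- function(set, model_a, model_b, orthologs,
                                eps = growth_eps()) {
  if (set$lethal_in == "A") {
    lethal <- model_a; survivor <- model_b
    del_l <- set$genes_a; del_s <- set$genes_b
    mapped_l <- orthologs$gene_a; mapped_s <- orthologs$gene_b
  } else {
    lethal <- model_b; survivor <- model_a
    del_l <- set$genes_b; del_s <- set$genes_a
    mapped_l <- orthologs$gene_b; mapped_s <- orthologs$gene_a
  }
  disabled <- lethal$rxns$id[vapply(lethal$rxns$id, function(rid) {
    g <- lethal$gpr[[rid]]
    !is.null(g) && !gpr_eval(g, deleted = del_l)
  }, logical(1))]

  ## survivor's optimal flux after the deletion, for rescue reporting
  surv_sol <- solve_fba(if (length(del_s) > 0L) knock_out(survivor, del_s)
                        else survivor)
  active <- if (surv_sol$status == "optimal") {
    names(surv_sol$fluxes)[abs(surv_sol$fluxes) > eps]
  } else character(0)

  all_rescued <- TRUE
  genetic_evidence <- FALSE
  orthology_evidence <- FALSE
  for (rid in disabled) {
    if (!(rid %in% survivor$rxns$id)) { all_rescued <- FALSE; next }
    gs <- survivor$gpr[[rid]]
    if (!is.null(gs) && !gpr_eval(gs, deleted = del_s)) {
      all_rescued <- FALSE
      next
    }
    rescuing <- setdiff(gpr_genes(gs), del_s)
    lethal_deleted_here <- intersect(gpr_genes(lethal$gpr[[rid]]), del_l)
    shaped_orthology <- length(rescuing) > 0L &&
      any(!(rescuing %in% mapped_s)) &&
      any(!(lethal_deleted_here %in% mapped_l))
    if (shaped_orthology) orthology_evidence <- TRUE
    else genetic_evidence <- TRUE
  }

  if (all_rescued && length(disabled) > 0L) {
    cat_label <- if (genetic_evidence) "genetic" else "orthology"
    rescue <- intersect(disabled, active)
    return(list(category = cat_label, rescue = rescue,
                low_confidence = FALSE))
  }
  unique_active <- setdiff(active, lethal$rxns$id)
  counterpart_active <- intersect(intersect(disabled, survivor$rxns$id),
                                  active)
  rescue <- union(unique_active, counterpart_active)
  list(category = "metabolic", rescue = rescue,
       low_confidence = length(unique_active) == 0L)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s vs %s: %d differential deletion set(s) (%d units, sets up to size %d)\n",
              x$model_a, x$model_b, length(x$sets), x$n_units,
              x$max_set_size))
  for (s in x$sets) {
    cat(sprintf("  {%s}: lethal in %s (mu_A %.3g, mu_B %.3g), %s%s\n",
                paste(s$units, collapse = ", "), s$lethal_in, s$mu_a, s$mu_b,
                s$category,
                if (length(s$rescue) > 0L)
                  paste0("; rescue: ", paste(s$rescue, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Differential deletion sets as a data frame
#'
#' @param comparison a `model_comparison`.
#' @return data frame with one row per set.
#' @export
comparison_table <- function(comparison) {
  if (length(comparison$sets) == 0L) {
    return(data.frame(units = character(0), lethal_in = character(0),
                      mu_a = numeric(0), mu_b = numeric(0),
                      category = character(0), rescue = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(comparison$sets, function(s) {
    data.frame(units = paste(s$units, collapse = "+"),
               lethal_in = s$lethal_in, mu_a = s$mu_a, mu_b = s$mu_b,
               category = s$category,
               rescue = paste(s$rescue, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
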