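# Flux balance analysis: medium application, gene knockouts, and the
# steady-state LP max c'v s.t. S v = 0, lb <= v <= ub.

#' Growth/no-growth threshold
#'
#' Growth rates below this value (1e-6 per hour) are treated as "no growth"
#' throughout the package; LP solvers routinely return tiny nonzero optima
#' for infeasible growth, so exact zero is never tested.
#'
#' @return the threshold, in 1/h.
#' @export
growth_eps <- function() 1e-6

#' Create a medium specification
#'
#' A medium maps exchange-reaction ids to maximum uptake rates
#' (mmol/gDW/h, non-negative).
#'
#' @param ... named rates, or a single named numeric vector / data frame
#'   with columns `exchange_id`, `max_uptake`.
#' @return a named numeric vector of class `medium_spec`.
#' @export
medium_spec <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots))) {
    x <- dots[[1L]]
    if (is.data.frame(x)) {
      rates <- stats::setNames(as.numeric(x$max_uptake), x$exchange_id)
    } else {
      rates <- x
    }
  } else {
    rates <- unlist(dots)
  }
  if (length(rates) > 0L && (is.null(names(rates)) || any(!nzchar(names(rates))))) {
    stop("medium rates must be named by exchange-reaction id")
  }
  if (any(rates < 0)) stop("medium uptake rates must be non-negative")
  structure(as.numeric(rates), names = names(rates), class = "medium_spec")
}

#' Read a medium specification from TSV
#'
#' Expects columns `exchange_id` and `max_uptake`.
#'
#' @param path file path.
#' @return a [medium_spec()].
#' @export
read_medium_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("exchange_id", "max_uptake") %in% names(df))) {
    stop("medium TSV needs columns 'exchange_id' and 'max_uptake'")
  }
  medium_spec(df)
}

#' Apply a growth medium to a model
#'
#' Sets the lower bound of every exchange reaction to `-rate` for exchanges
#' listed in the medium and to 0 otherwise (uptake closed). Secretion
#' (upper) bounds are untouched. Idempotent.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium_spec()] or named numeric vector of uptake rates.
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium) {
  if (!inherits(medium, "medium_spec")) medium <- medium_spec(medium)
  ex <- exchange_ids(model)
  unknown <- setdiff(names(medium), ex)
  if (length(unknown) > 0L) {
    stop("medium lists ids that are not exchange reactions in the model: ",
         paste(unknown, collapse = ", "))
  }
  k <- match(ex, model$rxns$id)
  model$rxns$lb[k] <- 0
  if (length(medium) > 0L) {
    kk <- match(names(medium), model$rxns$id)
    model$rxns$lb[kk] <- -unname(medium)
  }
  model
}

#' Delete genes from a model
#'
#' Every reaction whose GPR evaluates to `FALSE` with the given genes
#' removed has its bounds set to (0, 0). Reactions without a GPR are never
#' affected.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of gene ids to delete; unknown ids are an
#'   error.
#' @return the constrained model.
#' @export
knock_out <- function(model, genes) {
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown) > 0L) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  for (rid in model$rxns$id) {
    g <- model$gpr[[rid]]
    if (is.null(g)) next
    if (!gpr_eval(g, deleted = genes)) {
      model <- set_bounds(model, rid, lb = 0, ub = 0)
    }
  }
  model
}

#' Solve the FBA linear program of a model
#'
#' Maximizes the flux of the model's objective (biomass) reaction subject
#' to steady state (`S v = 0`) and the flux bounds.
#'
#' @param model a `metabolic_model` with `objective_id` set.
#' @param objective optional reaction id to maximize instead of the model
#'   objective (used e.g. by the energy-cycle detector).
#' @param maximize maximize (default) or minimize the objective flux.
#' @return an object of class `fba_solution`: `status` ("optimal",
#'   "infeasible" or "unbounded"), `objective_value` (the growth rate when
#'   the objective is biomass; `NA` unless optimal) and `fluxes` (named
#'   vector; `NA` unless optimal).
#' @export
solve_fba <- function(model, objective = NULL, maximize = TRUE) {
  if (is.null(objective)) {
    if (is.na(model$objective_id)) {
      stop(sprintf("model '%s' has no objective reaction", model$id))
    }
    objective <- model$objective_id
  }
  k <- rxn_index(model, objective)
  S <- as.matrix(build_stoich_matrix(model))
  n <- nrow(model$rxns)
  obj <- numeric(n)
  obj[k] <- 1
  res <- lp_solve(obj, S, rep(0, nrow(S)), model$rxns$lb, model$rxns$ub,
                  maximize = maximize)
  fluxes <- if (res$status == "optimal") {
    stats::setNames(res$x, model$rxns$id)
  } else {
    stats::setNames(rep(NA_real_, n), model$rxns$id)
  }
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 objective_id = objective,
                 fluxes = fluxes,
                 model_id = model$id),
            class = "fba_solution")
}

#' Flux balance analysis with medium and knockouts
#'
#' Convenience front end: applies a medium, imposes gene deletions, and
#' solves the growth-maximization LP.
#'
#' @param model a `metabolic_model`.
#' @param medium optional [medium_spec()].
#' @param knockouts optional character vector of gene ids to delete.
#' @return an `fba_solution` (see [solve_fba()]).
#' @examples
#' toy <- make_core_toy()
#' sol <- fba(toy$model, medium = toy$medium)
#' sol$objective_value
#' @export
fba <- function(model, medium = NULL, knockouts = NULL) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (!is.null(knockouts) && length(knockouts) > 0L) {
    model <- knock_out(model, knockouts)
  }
  solve_fba(model)
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution> model %s, objective %s\n", x$model_id,
              x$objective_id))
  if (x$status == "optimal") {
    cat(sprintf("  status optimal, value %.6g\n", x$objective_value))
  } else {
    cat(sprintf("  status %s\n", x$status))
  }
  invisible(x)
}

#' @export
coef.fba_solution <- function(object, ...) object$fluxes

#' @export
summary.fba_solution <- function(object, ...) {
  active <- sum(abs(object$fluxes) > growth_eps(), na.rm = TRUE)
  cat(sprintf("FBA on %s: status %s, objective %.6g, %d active fluxes\n",
              object$model_id, object$status,
              if (is.na(object$objective_value)) NaN else object$objective_value,
              active))
  invisible(object)
}

## growth rate convenience: NA -> 0 is deliberately NOT done; infeasible
## models report NA and callers must decide.
mu_of <- function(sol) {
  if (sol$status == "optimal") sol$objective_value else NA_real_
}

## growth yes/no under the shared threshold; infeasible counts as no growth
grows <- function(sol, eps = growth_eps()) {
  sol$status == "optimal" && sol$objective_value >= eps
}
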