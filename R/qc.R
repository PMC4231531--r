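# Curation checks: elemental/charge balance of reactions and detection of
# thermodynamically infeasible energy-generating cycles (free ATP with all
# exchanges closed).

#' Parse a chemical formula in Hill notation
#'
#' Supports element symbols with integer or decimal counts and
#' parenthesized groups with multipliers, e.g. `"C6H12O6"`,
#' `"Ca(OH)2"`. `"null"`, `"none"`, empty and `NA` are treated as unknown.
#'
#' @param text formula string.
#' @return named numeric vector of atom counts per element, or `NULL` when
#'   the formula is unknown or unparseable.
#' @export
parse_formula <- function(text) {
  if (is.null(text) || length(text) != 1L || is.na(text)) return(NULL)
  text <- trimws(text)
  ## "Na" is sodium, so the unknown markers are matched case-sensitively for
  ## the all-caps NA form and case-insensitively otherwise
  if (!nzchar(text) || identical(text, "NA") ||
      tolower(text) %in% c("null", "none", "unknown")) {
    return(NULL)
  }
  i <- 1L
  n <- nchar(text)
  peek <- function() if (i <= n) substr(text, i, i) else ""
  read_count <- function() {
    start <- i
    while (i <= n && grepl("[0-9.]", substr(text, i, i))) i <<- i + 1L
    if (i == start) return(1)
    as.numeric(substr(text, start, i - 1L))
  }
  parse_group <- function() {
    counts <- numeric(0)
    add <- function(el, k) {
      counts[el] <<- ifelse(is.na(counts[el]), 0, counts[el]) + k
    }
    while (i <= n) {
      ch <- peek()
      if (ch == ")") break
      if (ch == "(") {
        i <<- i + 1L
        inner <- parse_group()
        if (peek() != ")") return(NULL)
        i <<- i + 1L
        mult <- read_count()
        if (is.null(inner)) return(NULL)
        for (el in names(inner)) add(el, inner[[el]] * mult)
      } else if (grepl("[A-Z]", ch)) {
        el <- ch
        i <<- i + 1L
        while (i <= n && grepl("[a-z]", substr(text, i, i))) {
          el <- paste0(el, substr(text, i, i))
          i <<- i + 1L
        }
        add(el, read_count())
      } else {
        return(NULL)
      }
    }
    counts
  }
  out <- parse_group()
  if (is.null(out) || i <= n) return(NULL)   # trailing garbage
  out
}

#' Mass- and charge-balance check of one reaction
#'
#' Sums coefficient-weighted atoms per element over substrates and
#' products; charge is treated as an extra element row. Exchange, sink and
#' biomass reactions are boundary constructs and report verdict
#' `"exempt"`.
#'
#' @param rx a [reaction()] object, or a reaction id when `model` is given.
#' @param model a `metabolic_model` supplying the metabolite catalog
#'   (formulas and charges).
#' @return a list of class `balance_report`: `reaction_id`,
#'   `element_diff` (named numeric, products minus substrates),
#'   `charge_diff`, `verdict` (`"balanced"`, `"unbalanced"`,
#'   `"undetermined"` or `"exempt"`), `undetermined_mets`.
#' @export
check_balance <- function(rx, model) {
  if (is.character(rx)) {
    rid <- rx
    k <- rxn_index(model, rid)
    rx <- list(id = rid, stoich = model$stoich[[rid]],
               kind = model$rxns$kind[k])
  }
  rep0 <- function(verdict, diff = numeric(0), charge = NA_real_,
                   und = character(0)) {
    structure(list(reaction_id = rx$id, element_diff = diff,
                   charge_diff = charge, verdict = verdict,
                   undetermined_mets = und),
              class = "balance_report")
  }
  if (rx$kind %in% c("exchange", "sink", "biomass")) return(rep0("exempt"))

  met_row <- function(mid) model$mets[match(mid, model$mets$id), ]
  diff <- numeric(0)
  charge <- 0
  und <- character(0)
  charge_known <- TRUE
  for (mid in names(rx$stoich)) {
    mr <- met_row(mid)
    f <- parse_formula(mr$formula)
    if (is.null(f)) {
      und <- c(und, mid)
    } else {
      for (el in names(f)) {
        diff[el] <- ifelse(is.na(diff[el]), 0, diff[el]) +
          rx$stoich[[mid]] * f[[el]]
      }
    }
    if (is.na(mr$charge)) charge_known <- FALSE
    else charge <- charge + rx$stoich[[mid]] * mr$charge
  }
  if (length(und) > 0L) {
    return(rep0("undetermined", und = und))
  }
  diff <- diff[abs(diff) > 1e-9]
  charge_diff <- if (charge_known) charge else NA_real_
  verdict <- if (length(diff) == 0L &&
                 (!charge_known || abs(charge) < 1e-9)) {
    if (charge_known) "balanced" else "undetermined"
  } else if (length(diff) == 0L && charge_known && abs(charge) >= 1e-9) {
    "unbalanced"
  } else {
    "unbalanced"
  }
  rep0(verdict, diff = diff, charge = charge_diff)
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %s: %s\n", x$reaction_id, x$verdict))
  if (length(x$element_diff) > 0L) {
    cat("  element diff:",
        paste(sprintf("%s:%+g", names(x$element_diff), x$element_diff),
              collapse = " "), "\n")
  }
  if (!is.na(x$charge_diff) && abs(x$charge_diff) > 1e-9) {
    cat(sprintf("  charge diff: %+g\n", x$charge_diff))
  }
  if (length(x$undetermined_mets) > 0L) {
    cat("  unknown formulas:", paste(x$undetermined_mets, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Balance report for every metabolic reaction of a model
#'
#' @param model a `metabolic_model`.
#' @return data frame with columns `reaction_id`, `verdict`, `detail`.
#' @export
check_model_balance <- function(model) {
  rids <- model$rxns$id[model$rxns$kind == "metabolic"]
  reports <- lapply(rids, check_balance, model = model)
  data.frame(
    reaction_id = rids,
    verdict = vapply(reports, `[[`, character(1), "verdict"),
    detail = vapply(reports, function(r) {
      if (r$verdict == "unbalanced") {
        paste(c(sprintf("%s:%+g", names(r$element_diff), r$element_diff),
                if (!is.na(r$charge_diff) && abs(r$charge_diff) > 1e-9)
                  sprintf("charge:%+g", r$charge_diff)),
              collapse = " ")
      } else if (r$verdict == "undetermined") {
        paste(r$undetermined_mets, collapse = ",")
      } else ""
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Detect thermodynamically infeasible energy-generating cycles
#'
#' Closes every exchange reaction completely (both bounds 0), adds an
#' energy-dissipation reaction (by default ATP hydrolysis,
#' `atp_c + h2o_c -> adp_c + pi_c + h_c`, reduced to the metabolites the
#' model actually contains) and maximizes its flux. Any flux above the
#' growth threshold proves an internal cycle generating the energy
#' currency from nothing. A witness set of cycle reactions is extracted by
#' minimizing the L1 flux norm among optima (default) or, with
#' `witness = "cardinality"`, the number of active reactions (MILP).
#'
#' @param model a `metabolic_model`.
#' @param dissipation named numeric vector: the stoichiometry of the
#'   dissipation reaction. The default is ATP hydrolysis restricted to the
#'   metabolites present in the model (at minimum `atp_c` and `adp_c`).
#' @param witness `"l1"` (default) or `"cardinality"`.
#' @param eps threshold on the dissipation flux.
#' @return list of class `cycle_report`: `verdict` (`"clean"` or
#'   `"infeasible-cycle"`), `dissipation_flux`, `witness` (reaction ids),
#'   `dissipation_id`.
#' @export
detect_energy_cycles <- function(model,
                                 dissipation = NULL,
                                 witness = c("l1", "cardinality"),
                                 eps = growth_eps()) {
  witness <- match.arg(witness)
  if (is.null(dissipation)) {
    full <- c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1)
    dissipation <- full[names(full) %in% model$mets$id]
    if (!all(c("atp_c", "adp_c") %in% names(dissipation))) {
      stop("default dissipation needs metabolites 'atp_c' and 'adp_c' in the model")
    }
  }
  missing <- setdiff(names(dissipation), model$mets$id)
  if (length(missing) > 0L) {
    stop("dissipation metabolites absent from model: ",
         paste(missing, collapse = ", "))
  }
  diss_id <- "energy_dissipation__"
  m <- model
  ex <- exchange_ids(m)
  for (rid in ex) m <- set_bounds(m, rid, lb = 0, ub = 0)
  m <- add_reactions(m, reaction(diss_id, dissipation, lb = 0, ub = 1000,
                                 kind = "metabolic"))
  sol <- solve_fba(m, objective = diss_id)
  flux <- if (sol$status == "optimal") sol$objective_value else 0
  if (sol$status == "unbounded") flux <- Inf

  if (!is.finite(flux) || flux > eps) {
    wit <- cycle_witness(m, diss_id, min(flux, 1), witness)
    return(structure(list(verdict = "infeasible-cycle",
                          dissipation_flux = flux,
                          witness = wit$ids, witness_fluxes = wit$fluxes,
                          dissipation_id = diss_id),
                     class = "cycle_report"))
  }
  structure(list(verdict = "clean", dissipation_flux = flux,
                 witness = character(0), witness_fluxes = numeric(0),
                 dissipation_id = diss_id),
            class = "cycle_report")
}

## extract a small active set sustaining the dissipation flux
cycle_witness <- function(m, diss_id, level, witness) {
  S <- as.matrix(build_stoich_matrix(m))
  n <- ncol(S); nm <- nrow(S)
  lb <- m$rxns$lb; ub <- m$rxns$ub
  k <- rxn_index(m, diss_id)
  lb[k] <- level; ub[k] <- level
  if (witness == "l1") {
    ## min sum t  s.t.  S v = 0,  v - t <= 0,  -v - t <= 0
    A <- rbind(cbind(S, matrix(0, nm, n)),
               cbind(diag(n), -diag(n)),
               cbind(-diag(n), -diag(n)))
    dir <- c(rep("=", nm), rep("<=", 2 * n))
    rhs <- rep(0, nm + 2 * n)
    obj <- c(rep(0, n), rep(1, n))
    res <- lp_solve_mixed(obj, A, dir, rhs,
                          lb = c(lb, rep(0, n)),
                          ub = c(ub, pmax(abs(lb), abs(ub))),
                          maximize = FALSE)
    if (res$status != "optimal") return(list(ids = character(0),
                                             fluxes = numeric(0)))
    v <- res$x[seq_len(n)]
  } else {
    ## min sum z  s.t.  S v = 0,  v <= ub z,  v >= lb z,  z binary
    big <- pmax(abs(lb), abs(ub), 1)
    A <- rbind(cbind(S, matrix(0, nm, n)),
               cbind(diag(n), -diag(big)),
               cbind(-diag(n), -diag(big)))
    dir <- c(rep("=", nm), rep("<=", 2 * n))
    rhs <- rep(0, nm + 2 * n)
    obj <- c(rep(0, n), rep(1, n))
    res <- milp_solve(obj, A, dir, rhs,
                      lb = c(lb, rep(0, n)), ub = c(ub, rep(1, n)),
                      int_idx = n + seq_len(n), maximize = FALSE)
    if (res$status != "optimal") return(list(ids = character(0),
                                             fluxes = numeric(0)))
    v <- res$x[seq_len(n)]
  }
  v <- stats::setNames(v, m$rxns$id)
  act <- m$rxns$id[abs(v) > 1e-6]
  act <- setdiff(act, diss_id)
  list(ids = act, fluxes = v[act])
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle_report> verdict %s (dissipation flux %.6g)\n",
              x$verdict, x$dissipation_flux))
  if (length(x$witness) > 0L) {
    cat("  witness:", paste(x$witness, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Suggest directionality fixes for an energy cycle
#'
#' For each witness reaction, proposes forbidding the direction it carries
#' in the detected cycle (the "breaking direction"): a reaction running
#' forward gets its upper bound cut to 0, one running backward its lower
#' bound raised to 0. Proposals are advisory; the model is never modified.
#'
#' @param model the model that produced the report.
#' @param report a `cycle_report` with verdict `"infeasible-cycle"`.
#' @return data frame with columns `reaction_id`, `cycle_flux`,
#'   `suggested_lb`, `suggested_ub`.
#' @export
suggest_cycle_fixes <- function(model, report) {
  empty <- data.frame(reaction_id = character(0), cycle_flux = numeric(0),
                      suggested_lb = numeric(0), suggested_ub = numeric(0),
                      stringsAsFactors = FALSE)
  if (report$verdict != "infeasible-cycle") return(empty)
  out <- lapply(report$witness, function(rid) {
    k <- rxn_index(model, rid)
    v <- report$witness_fluxes[[rid]]
    if (v > 0) {
      data.frame(reaction_id = rid, cycle_flux = v,
                 suggested_lb = model$rxns$lb[k], suggested_ub = 0,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(reaction_id = rid, cycle_flux = v,
                 suggested_lb = 0, suggested_ub = model$rxns$ub[k],
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(out, list(empty)))
}
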