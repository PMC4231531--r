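# Plain tabular model exchange format.
#
# Reactions: TSV with columns rxn_id, equation, lb, ub, gpr, kind. The
# equation uses "<=>" (reversible) or "=>" arrows, terms joined by " + ",
# optional leading coefficients: "glc_c + atp_c => g6p_c + adp_c". A side
# may be empty (exchange/sink drains: "glc_e =>").
#
# Metabolites (optional companion table): TSV with columns met_id, name,
# compartment, formula, charge.

parse_equation <- function(eq, rid) {
  eq <- trimws(eq)
  rev_arrow <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (rev_arrow) "<=>" else "=>"
  if (!grepl(arrow, eq, fixed = TRUE)) {
    stop(sprintf("reaction '%s': equation lacks an arrow ('=>' or '<=>')", rid))
  }
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1L]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) next
      bits <- strsplit(tm, "[[:space:]]+")[[1L]]
      if (length(bits) == 2L) {
        coef <- suppressWarnings(as.numeric(bits[1L]))
        if (is.na(coef)) {
          stop(sprintf("reaction '%s': bad coefficient in term '%s'", rid, tm))
        }
        out[bits[2L]] <- sign * coef + ifelse(is.na(out[bits[2L]]), 0, out[bits[2L]])
      } else if (length(bits) == 1L) {
        out[bits[1L]] <- sign + ifelse(is.na(out[bits[1L]]), 0, out[bits[1L]])
      } else {
        stop(sprintf("reaction '%s': cannot parse term '%s'", rid, tm))
      }
    }
    out
  }
  lhs <- parse_side(sides[1L], -1)
  rhs <- parse_side(sides[2L], +1)
  st <- lhs
  for (mid in names(rhs)) {
    st[mid] <- ifelse(is.na(st[mid]), 0, st[mid]) + rhs[[mid]]
  }
  list(stoich = st[st != 0], reversible = rev_arrow)
}

format_equation <- function(stoich, reversible) {
  fmt_side <- function(st) {
    if (length(st) == 0L) return("")
    paste(ifelse(st == 1, names(st), paste(format(st, trim = TRUE), names(st))),
          collapse = " + ")
  }
  lhs <- -stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt_side(lhs), if (reversible) "<=>" else "=>", fmt_side(rhs))
}

#' Read a model from tabular reaction (and optional metabolite) files
#'
#' @param path reaction TSV with columns `rxn_id`, `equation`, `lb`, `ub`,
#'   `gpr`, `kind`. Missing `lb`/`ub` entries get the defaults
#'   (-1000, 1000) for `<=>` equations and (0, 1000) for `=>`.
#' @param met_path optional metabolite TSV with columns `met_id`, `name`,
#'   `compartment`, `formula`, `charge`; metabolites not listed are created
#'   with compartments inferred from their id suffixes.
#' @param id model id (defaults to the file name).
#' @param require_objective error when no `biomass`-kind row exists
#'   (default). With `FALSE` the objective is left unset.
#' @return a `metabolic_model`.
#' @export
read_model_tsv <- function(path, met_path = NULL,
                           id = sub("\\.[^.]*$", "", basename(path)),
                           require_objective = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("rxn_id", "equation")
  if (!all(need %in% names(df))) {
    stop("reaction TSV needs at least columns 'rxn_id' and 'equation'")
  }
  if (is.null(df$gpr)) df$gpr <- NA_character_
  if (is.null(df$kind)) df$kind <- "metabolic"
  if (is.null(df$lb)) df$lb <- NA_real_
  if (is.null(df$ub)) df$ub <- NA_real_

  rxns <- vector("list", nrow(df))
  met_ids <- character(0)
  for (i in seq_len(nrow(df))) {
    pe <- parse_equation(df$equation[i], df$rxn_id[i])
    lb <- df$lb[i]; ub <- df$ub[i]
    rxns[[i]] <- reaction(
      id = df$rxn_id[i], stoich = pe$stoich,
      name = if (!is.null(df$name)) df$name[i] else df$rxn_id[i],
      lb = if (is.na(lb)) NULL else lb,
      ub = if (is.na(ub)) NULL else ub,
      gpr = if (is.na(df$gpr[i])) NULL else df$gpr[i],
      kind = df$kind[i], reversible = pe$reversible)
    met_ids <- union(met_ids, names(pe$stoich))
  }

  met_tab <- NULL
  if (!is.null(met_path)) {
    met_tab <- utils::read.delim(met_path, stringsAsFactors = FALSE,
                                 na.strings = c("NA", ""))
  }
  mets <- lapply(met_ids, function(mid) {
    if (!is.null(met_tab) && mid %in% met_tab$met_id) {
      r <- met_tab[match(mid, met_tab$met_id), ]
      metabolite(mid,
                 name = if (!is.null(r$name) && !is.na(r$name)) r$name else mid,
                 compartment = if (!is.null(r$compartment) && !is.na(r$compartment))
                   r$compartment else infer_compartment(mid),
                 formula = if (!is.null(r$formula)) r$formula else NA_character_,
                 charge = if (!is.null(r$charge)) r$charge else NA_integer_)
    } else {
      metabolite(mid)
    }
  })

  obj <- df$rxn_id[df$kind == "biomass"]
  if (length(obj) == 0L) {
    if (require_objective) {
      stop(sprintf("no objective: model '%s' has no biomass reaction", id))
    }
    obj <- NA_character_
  }
  metabolic_model(id, mets, rxns, objective_id = obj[1L])
}

#' Write a model to tabular reaction (and optional metabolite) files
#'
#' @param model a `metabolic_model`.
#' @param path output reaction TSV path.
#' @param met_path optional output metabolite TSV path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path, met_path = NULL) {
  eqs <- vapply(model$rxns$id, function(rid) {
    format_equation(model$stoich[[rid]], model$rxns$lb[rxn_index(model, rid)] < 0)
  }, character(1))
  gprs <- vapply(model$rxns$id, function(rid) gpr_to_string(model$gpr[[rid]]),
                 character(1))
  df <- data.frame(rxn_id = model$rxns$id, name = model$rxns$name,
                   equation = unname(eqs), lb = model$rxns$lb,
                   ub = model$rxns$ub, gpr = unname(gprs),
                   kind = model$rxns$kind, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(met_path)) {
    utils::write.table(
      data.frame(met_id = model$mets$id, name = model$mets$name,
                 compartment = model$mets$compartment,
                 formula = model$mets$formula, charge = model$mets$charge,
                 stringsAsFactors = FALSE),
      met_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
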