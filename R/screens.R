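# In-silico phenotype screens: single amino-acid omission and carbohydrate
# utilization, plus accuracy scoring against observed call tables.
#
# Calls: amino acids R (required) / NR (not required); carbohydrates
# G (growth) / NG (no growth). Observed tables may additionally contain
# W (weak growth), which the default scoring policy counts as growth, so
# a W observation agrees with an NR or G prediction.

#' Single amino-acid omission screen
#'
#' Solves FBA on the full medium, then for each amino acid closes only its
#' exchange (uptake bound 0) and re-solves; a maximum growth rate below the
#' growth threshold calls the amino acid R (required), otherwise NR. The
#' input model is never modified (screens are side-effect free).
#'
#' @param model a `metabolic_model`.
#' @param medium the full medium (must support growth, else an error).
#' @param aa_exchanges named character vector: amino acid -> exchange id.
#' @param eps growth threshold.
#' @return a data frame of class `phenotype_calls` with columns `compound`,
#'   `exchange`, `baseline_mu`, `test_mu`, `predicted`; attribute
#'   `screen = "amino_acid"`.
#' @export
scan_amino_acids <- function(model, medium, aa_exchanges,
                             eps = growth_eps()) {
  m0 <- apply_medium(model, medium)
  base <- solve_fba(m0)
  if (!grows(base, eps)) {
    stop(sprintf("model '%s' does not grow on the full medium (status %s)",
                 model$id, base$status))
  }
  unknown <- setdiff(aa_exchanges, exchange_ids(model))
  if (length(unknown) > 0L) {
    stop("amino-acid exchanges not in model: ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(names(aa_exchanges), function(aa) {
    ex <- aa_exchanges[[aa]]
    med2 <- medium[setdiff(names(medium), ex)]
    sol <- solve_fba(apply_medium(model, medium_spec(med2)))
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    data.frame(compound = aa, exchange = ex,
               baseline_mu = base$objective_value, test_mu = mu,
               predicted = if (mu < eps) "R" else "NR",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "screen") <- "amino_acid"
  attr(out, "model_id") <- model$id
  class(out) <- c("phenotype_calls", "data.frame")
  out
}

#' Carbohydrate utilization screen
#'
#' Computes the baseline maximum growth rate on a carbohydrate-free medium
#' (typically essential amino acids only), then opens each carbohydrate's
#' uptake in turn; an increase of the growth rate beyond
#' `delta = max(eps, 0.01 * baseline)` calls the carbohydrate G, otherwise
#' NG. Compounds whose exchange id is `NA` or absent from the model are
#' called NG with reason `"no transporter"`.
#'
#' @param model a `metabolic_model`.
#' @param medium carbohydrate-free baseline medium.
#' @param carb_exchanges named character vector: compound -> exchange id
#'   (`NA` for compounds the model has no exchange for).
#' @param uptake_rate uptake cap for the carbohydrate under test
#'   (mmol/gDW/h).
#' @param eps growth threshold.
#' @return a `phenotype_calls` data frame with columns `compound`,
#'   `exchange`, `baseline_mu`, `test_mu`, `predicted`, `reason`.
#' @export
scan_carbohydrates <- function(model, medium, carb_exchanges,
                               uptake_rate = 10, eps = growth_eps()) {
  base <- solve_fba(apply_medium(model, medium))
  mu0 <- if (base$status == "optimal") base$objective_value else 0
  delta <- max(eps, 0.01 * mu0)
  ex_all <- exchange_ids(model)
  rows <- lapply(names(carb_exchanges), function(cb) {
    ex <- carb_exchanges[[cb]]
    if (is.na(ex) || !(ex %in% ex_all)) {
      return(data.frame(compound = cb, exchange = NA_character_,
                        baseline_mu = mu0, test_mu = mu0, predicted = "NG",
                        reason = "no transporter", stringsAsFactors = FALSE))
    }
    med2 <- medium_spec(c(stats::setNames(uptake_rate, ex), medium))
    sol <- solve_fba(apply_medium(model, med2))
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    data.frame(compound = cb, exchange = ex, baseline_mu = mu0, test_mu = mu,
               predicted = if (mu > mu0 + delta) "G" else "NG",
               reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "screen") <- "carbohydrate"
  attr(out, "model_id") <- model$id
  class(out) <- c("phenotype_calls", "data.frame")
  out
}

#' @export
print.phenotype_calls <- function(x, ...) {
  cat(sprintf("<phenotype_calls> %s screen, model %s: %d compounds\n",
              attr(x, "screen"), attr(x, "model_id"), nrow(x)))
  tb <- table(x$predicted)
  cat(" ", paste(sprintf("%s: %d", names(tb), as.integer(tb)),
                 collapse = ", "), "\n")
  invisible(x)
}

#' Score predicted against observed phenotype calls
#'
#' The positive outcome is growth: NR for the amino-acid screen (growth
#' without the compound), G for the carbohydrate screen. A false positive
#' is predicted growth where none was observed; a false negative is
#' predicted no growth where growth was observed. Observed `W` (weak
#' growth) is mapped by `w_policy`: `"growth"` (default) makes W agree
#' with NR/G predictions; `"no_growth"` makes it agree with R/NG.
#'
#' @param calls a `phenotype_calls` data frame.
#' @param observed named character vector (compound -> observed call) or a
#'   data frame with columns `compound` and `call`; every scored compound
#'   must be present. Valid symbols: R, NR, G, NG, W.
#' @param w_policy how to score observed weak growth.
#' @return a list of class `accuracy_report`: `n_compared`, `n_correct`,
#'   `false_positives`, `false_negatives` (counts), `discrepancies`
#'   (data frame), `table` (the merged per-compound table).
#' @export
score_predictions <- function(calls, observed,
                              w_policy = c("growth", "no_growth")) {
  w_policy <- match.arg(w_policy)
  if (is.data.frame(observed)) {
    observed <- stats::setNames(observed$call, observed$compound)
  }
  missing <- setdiff(calls$compound, names(observed))
  if (length(missing) > 0L) {
    stop("no observed call for: ", paste(missing, collapse = ", "))
  }
  obs <- observed[calls$compound]
  valid <- c("R", "NR", "G", "NG", "W")
  if (!all(obs %in% valid)) {
    stop("unknown observed symbol(s): ",
         paste(unique(obs[!(obs %in% valid)]), collapse = ", "))
  }
  screen <- attr(calls, "screen")
  pos <- if (identical(screen, "amino_acid")) "NR" else "G"
  neg <- if (identical(screen, "amino_acid")) "R" else "NG"
  to_binary <- function(x) {
    ifelse(x == "W", if (w_policy == "growth") pos else neg,
           ifelse(x %in% c("NR", "G"), pos, neg))
  }
  ob <- to_binary(obs)
  pr <- calls$predicted
  correct <- pr == ob
  fp <- pr == pos & ob == neg
  fn <- pr == neg & ob == pos
  tab <- data.frame(compound = calls$compound, predicted = pr,
                    observed = unname(obs), agrees = correct,
                    stringsAsFactors = FALSE)
  structure(list(
    n_compared = nrow(tab),
    n_correct = sum(correct),
    false_positives = sum(fp),
    false_negatives = sum(fn),
    discrepancies = tab[!correct, , drop = FALSE],
    table = tab,
    screen = screen,
    model_id = attr(calls, "model_id")
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %s screen, model %s\n", x$screen, x$model_id))
  cat(sprintf("  accuracy %d/%d (FP %d, FN %d)\n", x$n_correct, x$n_compared,
              x$false_positives, x$false_negatives))
  if (nrow(x$discrepancies) > 0L) {
    cat("  discrepancies:",
        paste(sprintf("%s (pred %s, obs %s)", x$discrepancies$compound,
                      x$discrepancies$predicted, x$discrepancies$observed),
              collapse = "; "), "\n")
  }
  invisible(x)
}
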