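# End-to-end screen-and-score workflow: QC -> amino-acid screen ->
# carbohydrate screen -> scoring -> (optional gap-fill of false negatives)
# -> two-model comparison, with per-stage TSV/JSON reports.

#' Run the full screen-and-score workflow on a strain bundle
#'
#' @param bundle a list shaped like [synthetic_strain_models()]: two models
#'   (`atcc334`, `l12a`), an ortholog map, media, compound-to-exchange
#'   maps and observed phenotype tables.
#' @param out_dir optional directory for TSV/JSON reports.
#' @param max_set_size deletion-set size cap for the comparison stage.
#' @param gapfill_db optional `reaction_database`; when given and a screen
#'   produces false negatives, a gap-fill is attempted for each
#'   false-negative compound and the screen is re-run.
#' @param eps growth threshold.
#' @return list of class `workflow_report` with per-stage results:
#'   `qc`, `amino_acids`, `carbohydrates` (per strain: calls + accuracy),
#'   `comparison` (per condition), `summary` (flat named list of the
#'   headline numbers).
#' @export
reproduce_workflow <- function(bundle = synthetic_strain_models(),
                               out_dir = NULL, max_set_size = 1L,
                               gapfill_db = NULL, eps = growth_eps()) {
  need <- c("atcc334", "l12a", "orthologs", "media",
            "amino_acid_exchanges", "carbohydrate_exchanges", "observed")
  missing <- setdiff(need, names(bundle))
  if (length(missing) > 0L) {
    stop("workflow bundle is missing: ", paste(missing, collapse = ", "))
  }
  strains <- c("atcc334", "l12a")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("workflow stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  qc <- stage("qc", lapply(stats::setNames(strains, strains), function(s) {
    model <- bundle[[s]]
    bal <- check_model_balance(model)
    cyc <- detect_energy_cycles(model)
    list(balance = table(bal$verdict), cycles = cyc$verdict,
         dissipation_flux = cyc$dissipation_flux)
  }))

  aa <- stage("amino_acid_screen",
              lapply(stats::setNames(strains, strains), function(s) {
    calls <- scan_amino_acids(bundle[[s]], bundle$media$cdm,
                              bundle$amino_acid_exchanges, eps = eps)
    obs <- stats::setNames(bundle$observed$amino_acids[[s]],
                           bundle$observed$amino_acids$compound)
    list(calls = calls, accuracy = score_predictions(calls, obs))
  }))

  carb <- stage("carbohydrate_screen",
                lapply(stats::setNames(strains, strains), function(s) {
    med <- bundle$media[[paste0("carb_baseline_", s)]]
    calls <- scan_carbohydrates(bundle[[s]], med,
                                bundle$carbohydrate_exchanges, eps = eps)
    obs <- stats::setNames(bundle$observed$carbohydrates[[s]],
                           bundle$observed$carbohydrates$compound)
    list(calls = calls, accuracy = score_predictions(calls, obs))
  }))

  gapfills <- list()
  if (!is.null(gapfill_db)) {
    gapfills <- stage("gapfill", {
      out <- list()
      for (s in strains) {
        fn <- carb[[s]]$accuracy$table
        fn <- fn$compound[!fn$agrees & fn$predicted == "NG"]
        for (compound in fn) {
          ex <- bundle$carbohydrate_exchanges[[compound]]
          if (is.na(ex)) next
          med <- bundle$media[[paste0("carb_baseline_", s)]]
          med2 <- medium_spec(c(stats::setNames(10, ex), med))
          out[[paste(s, compound, sep = ":")]] <-
            tryCatch(gapfill(bundle[[s]], gapfill_db, med2, eps = eps),
                     error = function(e) conditionMessage(e))
        }
      }
      out
    })
  }

  comparison <- stage("comparison", list(
    essential = compare_models(bundle$atcc334, bundle$l12a,
                               bundle$orthologs,
                               bundle$media$compare_essential,
                               max_set_size = max_set_size, eps = eps),
    all_amino_acids = compare_models(bundle$atcc334, bundle$l12a,
                                     bundle$orthologs,
                                     bundle$media$compare_all,
                                     max_set_size = max_set_size, eps = eps)
  ))

  summary <- list(
    aa_accuracy_atcc334 = sprintf("%d/%d", aa$atcc334$accuracy$n_correct,
                                  aa$atcc334$accuracy$n_compared),
    aa_accuracy_l12a = sprintf("%d/%d", aa$l12a$accuracy$n_correct,
                               aa$l12a$accuracy$n_compared),
    carb_accuracy_atcc334 = sprintf("%d/%d",
                                    carb$atcc334$accuracy$n_correct,
                                    carb$atcc334$accuracy$n_compared),
    carb_accuracy_l12a = sprintf("%d/%d", carb$l12a$accuracy$n_correct,
                                 carb$l12a$accuracy$n_compared),
    differential_sets_essential = length(comparison$essential$sets),
    differential_sets_all = length(comparison$all_amino_acids$sets)
  )

  report <- structure(list(qc = qc, amino_acids = aa, carbohydrates = carb,
                           gapfills = gapfills, comparison = comparison,
                           summary = summary),
                      class = "workflow_report")
  if (!is.null(out_dir)) write_workflow_report(report, out_dir)
  report
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("<workflow_report>\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-28s %s\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}

#' Write a workflow report to per-stage TSV/JSON files
#'
#' @param report a `workflow_report`.
#' @param out_dir output directory (created if needed).
#' @return character vector of files written.
#' @export
write_workflow_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  for (s in names(report$amino_acids)) {
    wt(report$amino_acids[[s]]$calls, sprintf("amino_acids_%s.tsv", s))
    wt(report$amino_acids[[s]]$accuracy$table,
       sprintf("amino_acids_%s_scored.tsv", s))
    wt(report$carbohydrates[[s]]$calls, sprintf("carbohydrates_%s.tsv", s))
    wt(report$carbohydrates[[s]]$accuracy$table,
       sprintf("carbohydrates_%s_scored.tsv", s))
  }
  for (cond in names(report$comparison)) {
    wt(comparison_table(report$comparison[[cond]]),
       sprintf("comparison_%s.tsv", cond))
  }
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(report$summary, sp, auto_unbox = TRUE, digits = NA)
  written <- c(written, sp)
  invisible(written)
}

#' Validate a workflow run configuration
#'
#' Checks, before any computation, that every referenced path exists and
#' the thresholds are positive.
#'
#' @param config a named list (typically from a JSON file): optional path
#'   fields (`model_a`, `model_b`, `medium`, `orthologs`, `database`,
#'   `observed_amino_acids`, `observed_carbohydrates`), optional numeric
#'   fields (`eps`, `delta`, `target_growth`, `max_set_size`), optional
#'   `out_dir` and `seed`.
#' @return the config, invisibly; errors on the first problem.
#' @export
validate_run_config <- function(config) {
  path_fields <- c("model_a", "model_b", "medium", "orthologs", "database",
                   "observed_amino_acids", "observed_carbohydrates")
  for (f in intersect(path_fields, names(config))) {
    if (!file.exists(config[[f]])) {
      stop(sprintf("config error: %s path does not exist: %s", f, config[[f]]))
    }
  }
  for (f in intersect(c("eps", "delta", "target_growth", "max_set_size"),
                      names(config))) {
    if (!is.numeric(config[[f]]) || config[[f]] <= 0) {
      stop(sprintf("config error: %s must be a positive number", f))
    }
  }
  invisible(config)
}
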