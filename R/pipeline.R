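#' Run the full kinome-activity pipeline
#'
#' Orchestrates filter -> quantify -> oxidation collapse -> differential
#' statistics -> ROC -> panel selection -> logistic panel fit -> clustering,
#' starting from a transition report, assay panel and cohort design (as
#' tibbles or file paths). Optionally writes every tabular artifact plus a
#' JSON run summary with stage counts, the resolved configuration and all
#' warnings raised along the way.
#'
#' @param transitions Transition tibble or path readable by
#'   [read_transition_report()].
#' @param panel Assay panel tibble or path.
#' @param design Cohort design tibble or path.
#' @param config A [filter_config()].
#' @param panel_rule `"six_kinase"` or `"four_kinase"` (see
#'   [select_panel()]).
#' @param var_equal Student (TRUE, default) or Welch t-test.
#' @param linkage Clustering linkage, see [hierarchical_cluster()].
#' @param min_per_group Minimum patients per class for the per-state tests.
#' @param p_adjust `"none"` or `"BH"`, see [diff_stats()].
#' @param out_dir Output directory; NULL (default) writes nothing.
#' @return List of class `kinact_run`: `filtered` (see
#'   [filter_transitions()]), `abundance_peptide`, `abundance` (state
#'   level), `detection`, `stats`, `panel_states`, `panel_fit`, `cluster`
#'   (NULL when fewer than 2 testable states), `summary` (stage counts,
#'   config, warnings).
#' @export
run_pipeline <- function(transitions, panel, design,
                         config = filter_config(),
                         panel_rule = c("four_kinase", "six_kinase"),
                         var_equal = TRUE,
                         linkage = "complete",
                         min_per_group = 2L,
                         p_adjust = "none",
                         out_dir = NULL) {
  panel_rule <- match.arg(panel_rule)
  warnings_log <- character()
  note <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  if (is.character(transitions)) transitions <- read_transition_report(transitions)
  if (is.character(panel)) panel <- read_assay_panel(panel)
  if (is.character(design)) design <- suppressMessages(read_sample_metadata(design))
  transitions <- validate_transitions(transitions)
  panel <- validate_assay_panel(as_tibble(panel))

  filtered <- note(filter_transitions(transitions, config))
  abundance_peptide <- note(compute_abundance(
    filtered$records, filtered$quant_set,
    min_transitions = config$min_transitions
  ))
  abundance <- note(collapse_oxidation(abundance_peptide, panel))
  detection <- detection_summary(abundance, design)
  stats_tbl <- note(diff_stats(abundance, design, var_equal = var_equal,
                               min_per_group = min_per_group,
                               p_adjust = p_adjust))
  panel_states <- note(select_panel(stats_tbl, panel_rule))
  panel_fit <- if (length(panel_states) > 0) {
    note(fit_logistic(abundance, design, panel_states))
  } else {
    NULL
  }
  testable <- stats_tbl$state_id[!is.na(stats_tbl$anova_p) &
                                   stats_tbl$anova_p < 0.05]
  cluster <- NULL
  if (length(testable) >= 2) {
    z <- note(zscore_rows(abundance_wide(
      abundance[abundance$state_id %in% testable, ]
    )))
    if (nrow(z) >= 2 && ncol(z) >= 3) {
      cluster <- note(hierarchical_cluster(z, linkage = linkage))
    }
  }
  summary <- list(
    stage_counts = as.list(filtered$stage_counts),
    n_quantified_peptides = length(unique(abundance_peptide$peptide_key)),
    n_activation_states = length(unique(abundance$state_id)),
    n_patients = nrow(design),
    panel_rule = panel_rule,
    panel_states = panel_states,
    panel_auc = if (!is.null(panel_fit)) panel_fit$auc else NA,
    config = unclass(config),
    options = list(var_equal = var_equal, linkage = linkage,
                   min_per_group = min_per_group, p_adjust = p_adjust),
    warnings = warnings_log
  )
  run <- structure(
    list(
      filtered = filtered,
      abundance_peptide = abundance_peptide,
      abundance = abundance,
      detection = detection,
      stats = stats_tbl,
      panel_states = panel_states,
      panel_fit = panel_fit,
      cluster = cluster,
      summary = summary
    ),
    class = "kinact_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_abundance_matrix(run$abundance, p("abundance_matrix.tsv"))
  write_stats_table(run$stats, p("stats_table.tsv"))
  readr::write_tsv(run$detection$per_patient, p("detection_per_patient.tsv"))
  readr::write_tsv(run$detection$per_state, p("detection_per_state.tsv"))
  readr::write_tsv(run$filtered$removed, p("removed_transitions.tsv"))
  if (!is.null(run$panel_fit)) {
    jsonlite::write_json(
      list(
        states = run$panel_fit$states,
        coefficients = as.list(run$panel_fit$coefficients),
        auc = run$panel_fit$auc,
        converged = run$panel_fit$converged
      ),
      p("panel_model.json"), auto_unbox = TRUE, digits = NA
    )
    readr::write_tsv(run$panel_fit$roc$curve, p("panel_roc_curve.tsv"))
  }
  if (!is.null(run$cluster)) {
    readr::write_tsv(
      tibble(order = seq_along(run$cluster$col_order),
             patient_id = run$cluster$col_order),
      p("cluster_column_order.tsv")
    )
  }
  jsonlite::write_json(run$summary, p("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.kinact_run <- function(x, ...) {
  sc <- x$summary$stage_counts
  cat("<kinact pipeline run>\n")
  cat(sprintf("  transitions: %d -> S/N %d -> contribution %d -> sparsity %d -> quantifiable %d\n",
              sc$input, sc$snr, sc$contribution, sc$sparsity, sc$quantifiable))
  cat(sprintf("  activation states: %d across %d patients\n",
              x$summary$n_activation_states, x$summary$n_patients))
  cat(sprintf("  panel (%s): %s; AUC = %s\n",
              x$summary$panel_rule,
              if (length(x$panel_states)) paste(x$panel_states, collapse = ", ")
              else "<empty>",
              if (is.na(x$summary$panel_auc)) "NA"
              else sprintf("%.3f", x$summary$panel_auc)))
  invisible(x)
}

#' Quality-control report: detection depth and replicate reproducibility
#'
#' @param abundance State-level abundance tibble.
#' @param design Cohort design.
#' @param replicates Optional character vector of two patient/sample ids
#'   that are technical replicates of the same biopsy; adds a
#'   replicate-correlation section.
#' @return List with `per_patient`, `per_state` (as [detection_summary()])
#'   and `replicate` (tibble or NULL).
#' @export
qc_report <- function(abundance, design, replicates = NULL) {
  abundance <- as_tibble(abundance)
  if (nrow(abundance) == 0) {
    warn("empty abundance matrix: QC report has no detections")
  }
  det <- detection_summary(abundance, design)
  rep_tbl <- NULL
  if (!is.null(replicates)) {
    stopifnot(length(replicates) == 2)
    rep_tbl <- replicate_correlation(abundance, replicates[1], replicates[2])
  }
  list(per_patient = det$per_patient, per_state = det$per_state,
       replicate = rep_tbl)
}
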