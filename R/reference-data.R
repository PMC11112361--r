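#' Reference per-kinase differential-activity statistics
#'
#' The published per-activation-state statistics of a 32-patient
#' neoadjuvant HER2+ breast cancer cohort (17 pCR / 6 npCR / 9 No pCR):
#' log2 fold change responders vs non-responders, t-test p-value, patients
#' detected (n and % of 32), single-kinase ROC AUC and its p-value, plus a
#' paralog-sharing flag. Twelve activation states reached significance and
#' are listed. The `"ERK2 (T185)"` t-test p-value was reported only as an
#' upper bound (< 0.001) and is stored as 0.001.
#'
#' Used as the input of the panel-selection rules (see [select_panel()]):
#' the detectability/fold-change rule picks the six-state HER2-pathway
#' panel, the stricter 100%-detection rule the four-state panel.
#'
#' @return Stats tibble with columns `state_id`, `log2_fc`, `ttest_p`,
#'   `n_detected`, `pct_detected`, `auc`, `roc_p`, `paralog_shared`.
#' @examples
#' select_panel(reference_kinase_stats(), "six_kinase")
#' @export
reference_kinase_stats <- function() {
  read_stats_table(
    system.file("extdata", "reference_kinase_stats.tsv", package = "kinact",
                mustWork = TRUE)
  )
}
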