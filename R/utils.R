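#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select group_by ungroup summarise arrange
#'   left_join inner_join anti_join semi_join across n distinct rename bind_rows
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd cor aov TukeyHSD pt pf pnorm qnorm glm binomial
#'   coef fitted hclust dist as.dendrogram order.dendrogram complete.cases
#'   setNames na.omit
NULL

# canonical column set of a transition report
transition_cols <- c(
  "sample_id", "peptide_key", "precursor_charge",
  "fragment_ion", "label", "area", "background"
)

transition_key_cols <- c(
  "sample_id", "peptide_key", "precursor_charge", "fragment_ion", "label"
)

#' Validate a transition tibble against its invariants
#'
#' Checks column presence, label values, non-negative intensities and
#' uniqueness of the (sample, peptide, charge, fragment, label) key.
#'
#' @param records A data frame of transition records.
#' @param call Calling environment for error reporting.
#' @return The validated records as a tibble (invisibly usable in pipes).
#' @keywords internal
validate_transitions <- function(records, call = rlang::caller_env()) {
  records <- as_tibble(records)
  missing_cols <- setdiff(transition_cols, names(records))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "transition report is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "kinact_format_error", call = call
    )
  }
  bad_label <- setdiff(unique(records$label), c("light", "heavy"))
  if (length(bad_label) > 0) {
    abort(
      paste0("label must be 'light' or 'heavy'; found: ",
             paste(bad_label, collapse = ", ")),
      class = "kinact_validation_error", call = call
    )
  }
  neg <- which(records$area < 0 | records$background < 0)
  if (length(neg) > 0) {
    abort(
      paste0("negative area or background at row ", neg[1]),
      class = "kinact_validation_error", call = call
    )
  }
  dup <- duplicated(records[transition_key_cols])
  if (any(dup)) {
    first <- records[which(dup)[1], transition_key_cols]
    abort(
      paste0(
        "duplicate transition key: ",
        paste(unlist(first), collapse = " / ")
      ),
      class = "kinact_integrity_error", call = call
    )
  }
  records
}

# stable order used by writers so outputs are byte-reproducible
arrange_transitions <- function(records) {
  dplyr::arrange(
    records, .data$sample_id, .data$peptide_key,
    .data$precursor_charge, .data$fragment_ion, .data$label
  )
}
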