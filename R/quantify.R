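#' Internal-standard-normalized T-loop abundance
#'
#' For each peptide and sample, the log2 abundance is
#' `log2(sum of light areas / sum of heavy areas)` over the fixed
#' quantification transition set. Because every light fragment is referenced
#' to the co-eluting heavy standard, per-sample spike amount and instrument
#' response cancel exactly.
#'
#' Only fragments of the quantification set observed in *both* labels in a
#' given sample enter the sums; a (peptide, sample) cell with fewer than
#' `min_transitions` such fragments, or a zero heavy sum, is left missing.
#'
#' @param records Filtered transition tibble.
#' @param quant_set Quantification set from [select_quant_transitions()].
#' @param min_transitions Minimum matched fragments per quantified cell.
#' @return Long peptide-level abundance tibble: `peptide_key`, `patient_id`,
#'   `log2_abundance`.
#' @examples
#' rec <- tibble::tibble(
#'   sample_id = "p1", peptide_key = "PEP", precursor_charge = 2L,
#'   fragment_ion = rep(c("y5", "y6"), 2),
#'   label = rep(c("light", "heavy"), each = 2),
#'   area = c(100, 100, 200, 200), background = 0
#' )
#' qs <- tibble::tibble(peptide_key = "PEP", fragment_ion = c("y5", "y6"))
#' compute_abundance(rec, qs)$log2_abundance  # log2(200/400) = -1
#' @export
compute_abundance <- function(records, quant_set,
                              min_transitions = 2L) {
  records <- as_tibble(records)
  use <- dplyr::inner_join(records, as_tibble(quant_set),
                           by = c("peptide_key", "fragment_ion"))
  wide <- tidyr::pivot_wider(
    use[c("sample_id", "peptide_key", "precursor_charge", "fragment_ion",
          "label", "area")],
    names_from = "label", values_from = "area"
  )
  for (lab in c("light", "heavy")) {
    if (!lab %in% names(wide)) wide[[lab]] <- NA_real_
  }
  wide <- wide[!is.na(wide$light) & !is.na(wide$heavy), ]
  out <- wide |>
    group_by(.data$sample_id, .data$peptide_key) |>
    summarise(
      n_frag = n(),
      light_sum = sum(.data$light),
      heavy_sum = sum(.data$heavy),
      .groups = "drop"
    ) |>
    filter(.data$n_frag >= min_transitions)
  zero_heavy <- out$heavy_sum <= 0
  if (any(zero_heavy)) {
    warn(sprintf(
      "%d peptide/sample cell(s) had a zero heavy sum and were set missing",
      sum(zero_heavy)
    ))
    out <- out[!zero_heavy, ]
  }
  tibble(
    peptide_key = out$peptide_key,
    patient_id = out$sample_id,
    log2_abundance = log2(out$light_sum / out$heavy_sum)
  ) |>
    dplyr::arrange(.data$peptide_key, .data$patient_id)
}

#' Collapse oxidized satellite peptides into kinase activation states
#'
#' Methionine-oxidized forms of a T-loop peptide report on the same
#' activation state at roughly 10-fold lower signal. Per sample: when both
#' oxidation forms are quantified only the non-oxidized value is used; when
#' a single form is present its value is used as-is. Rows are re-keyed to
#' activation states, labelled `"KINASE (SITE)"` (kinases joined with `/`
#' for paralog-shared peptides, sites with ` + ` for doubly phosphorylated
#' forms).
#'
#' @param abundance Peptide-level long abundance tibble.
#' @param panel Assay panel tibble (see [read_assay_panel()]).
#' @return State-level long abundance tibble: `state_id`, `patient_id`,
#'   `log2_abundance`, `kinases`, `sites`, `paralog_shared`, plus
#'   `from_oxidized` flagging cells where only the oxidized form was
#'   available.
#' @export
collapse_oxidation <- function(abundance, panel) {
  abundance <- as_tibble(abundance)
  panel <- as_tibble(panel)
  ann <- dplyr::left_join(abundance, panel, by = "peptide_key")
  if (anyNA(ann$kinases)) {
    bad <- unique(ann$peptide_key[is.na(ann$kinases)])
    abort(paste0("peptide(s) not in assay panel: ",
                 paste(utils::head(bad, 3), collapse = ", ")),
          class = "kinact_reference_error")
  }
  ann$state_id <- state_label(ann$kinases, ann$sites)
  collapsed <- ann |>
    group_by(.data$state_id, .data$patient_id) |>
    summarise(
      log2_abundance = if (any(!.data$is_oxidized)) {
        .data$log2_abundance[!.data$is_oxidized][1]
      } else {
        .data$log2_abundance[1]
      },
      from_oxidized = all(.data$is_oxidized),
      kinases = .data$kinases[1],
      sites = .data$sites[1],
      paralog_shared = .data$paralog_shared[1],
      .groups = "drop"
    )
  dplyr::arrange(collapsed, .data$state_id, .data$patient_id)
}

#' Compose the activation-state label used throughout reporting
#' @param kinases ";"-separated gene symbols.
#' @param sites ";"-separated site labels (with `+` for double phospho).
#' @return Character vector like `"ERK2 (T185)"` or `"p38A (T180 + Y182)"`.
#' @export
state_label <- function(kinases, sites) {
  k <- gsub(";", "/", kinases, fixed = TRUE)
  s <- gsub(";", " + ", sites, fixed = TRUE)
  paste0(k, " (", s, ")")
}

#' Per-patient and per-state detection summary
#'
#' @param abundance State-level long abundance tibble.
#' @param design Cohort design tibble ([cohort_design()]); patients with no
#'   detected states are reported with a zero count.
#' @return List with `per_patient` (patient_id, outcome, n_detected) and
#'   `per_state` (state_id, n_detected, pct_detected over the cohort).
#' @export
detection_summary <- function(abundance, design) {
  abundance <- as_tibble(abundance)
  design <- as_tibble(design)
  id_col <- intersect(c("state_id", "peptide_key"), names(abundance))[1]
  per_patient <- abundance |>
    group_by(.data$patient_id) |>
    summarise(n_detected = n(), .groups = "drop")
  per_patient <- dplyr::left_join(design[c("patient_id", "outcome")],
                                  per_patient, by = "patient_id")
  per_patient$n_detected[is.na(per_patient$n_detected)] <- 0L
  per_state <- abundance |>
    group_by(state_id = .data[[id_col]]) |>
    summarise(n_detected = n(), .groups = "drop") |>
    mutate(pct_detected = 100 * .data$n_detected / nrow(design))
  list(per_patient = per_patient, per_state = per_state)
}

#' Reproducibility of two workflow replicates
#'
#' Pearson correlation plus least-squares slope/intercept (replicate B
#' regressed on replicate A) over the activation states quantified in both.
#'
#' @param abundance Long abundance tibble containing both replicates.
#' @param sample_a,sample_b Patient/sample ids of the two replicates.
#' @return One-row tibble: `r`, `slope`, `intercept`, `n_shared`.
#' @export
replicate_correlation <- function(abundance, sample_a, sample_b) {
  abundance <- as_tibble(abundance)
  id_col <- intersect(c("state_id", "peptide_key"), names(abundance))[1]
  a <- abundance[abundance$patient_id == sample_a, c(id_col, "log2_abundance")]
  b <- abundance[abundance$patient_id == sample_b, c(id_col, "log2_abundance")]
  shared <- dplyr::inner_join(a, b, by = id_col, suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    abort("fewer than 3 activation states shared between replicates",
          class = "kinact_insufficient_data")
  }
  fit <- stats::lm(log2_abundance_b ~ log2_abundance_a, data = shared)
  tibble(
    r = cor(shared$log2_abundance_a, shared$log2_abundance_b),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n_shared = nrow(shared)
  )
}
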