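#' Read a transition-level quantification report
#'
#' Reads a delimited (tab or comma) export of integrated transition signals:
#' one row per sample x peptide form x precursor charge x fragment ion x
#' isotope label, with integrated area and background. Column names can be
#' remapped from whatever the peak-integration software exported via
#' `dialect`; extra columns are ignored.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector mapping canonical field names
#'   (`sample_id`, `peptide_key`, `precursor_charge`, `fragment_ion`,
#'   `label`, `area`, `background`) to the column names used in the file.
#'   Fields absent from the mapping are looked up under their canonical name.
#' @return A tibble of validated transition records. Labels are normalized
#'   case-insensitively to `"light"` / `"heavy"`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = c(3, 2, 2), n_targets = 10,
#'                                   n_detectable = 6,
#'                                   effects = c("ERK2 (T185)" = 1.1),
#'                                   seed = 1))
#' tf <- tempfile(fileext = ".tsv")
#' write_transition_report(sim$transitions, tf)
#' rec <- read_transition_report(tf)
#' nrow(rec) == nrow(sim$transitions)
#' @export
read_transition_report <- function(path, dialect = NULL) {
  raw <- read_delimited(path)
  for (field in transition_cols) {
    src <- if (!is.null(dialect) && field %in% names(dialect)) {
      dialect[[field]]
    } else {
      field
    }
    if (!src %in% names(raw)) {
      abort(
        paste0("column '", src, "' (field '", field, "') not found in ", path),
        class = "kinact_format_error"
      )
    }
    names(raw)[names(raw) == src] <- field
  }
  records <- raw[transition_cols]
  records$label <- tolower(trimws(records$label))
  records$precursor_charge <- as.integer(records$precursor_charge)
  records$area <- as.numeric(records$area)
  records$background <- as.numeric(records$background)
  validate_transitions(records)
}

#' Write a transition report
#'
#' @param records Transition tibble (see [read_transition_report()]).
#' @param path Output path; tab-separated UTF-8 with header.
#' @return `path`, invisibly.
#' @export
write_transition_report <- function(records, path) {
  records <- validate_transitions(records)
  readr::write_tsv(arrange_transitions(records), path)
  invisible(path)
}

#' Read a T-loop assay panel table
#'
#' The panel maps each targeted phosphopeptide form to the kinase(s) and
#' activation-loop site(s) it reports on, flags methionine-oxidized
#' satellite forms (linked to their non-oxidized partner) and peptides whose
#' sequence is shared across kinase paralogs.
#'
#' @param path Delimited text with columns `peptide_key`, `kinases`
#'   (";"-separated gene symbols), `sites` (";"-separated residue labels,
#'   `+` joining sites of one doubly phosphorylated form), `is_oxidized`,
#'   `n_phospho`, `paralog_shared`, `nonoxidized_partner` (empty when not
#'   oxidized).
#' @return A tibble of targets; oxidized rows have their partner resolved.
#' @export
read_assay_panel <- function(path) {
  panel <- read_delimited(path)
  req <- c("peptide_key", "kinases", "sites", "is_oxidized", "n_phospho",
           "paralog_shared", "nonoxidized_partner")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("assay panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "kinact_format_error")
  }
  panel <- as_tibble(panel[req])
  panel$is_oxidized <- as.logical(panel$is_oxidized)
  panel$paralog_shared <- as.logical(panel$paralog_shared)
  panel$n_phospho <- as.integer(panel$n_phospho)
  panel$nonoxidized_partner <- as.character(panel$nonoxidized_partner)
  panel$nonoxidized_partner[
    is.na(panel$nonoxidized_partner) | panel$nonoxidized_partner == ""
  ] <- NA_character_
  validate_assay_panel(panel)
}

validate_assay_panel <- function(panel, call = rlang::caller_env()) {
  stopifnot(all(panel$n_phospho %in% c(1L, 2L)))
  ox <- panel[panel$is_oxidized, ]
  if (nrow(ox) > 0) {
    dangling <- setdiff(ox$nonoxidized_partner, panel$peptide_key)
    dangling <- dangling[!is.na(dangling)]
    if (any(is.na(ox$nonoxidized_partner))) {
      abort("oxidized target without a nonoxidized_partner reference",
            class = "kinact_reference_error", call = call)
    }
    if (length(dangling) > 0) {
      abort(paste0("nonoxidized_partner not present in panel: ",
                   paste(dangling, collapse = ", ")),
            class = "kinact_reference_error", call = call)
    }
    partner <- panel[match(ox$nonoxidized_partner, panel$peptide_key), ]
    mismatch <- partner$kinases != ox$kinases | partner$sites != ox$sites
    if (any(mismatch)) {
      abort(paste0("oxidized form and partner disagree on kinases/sites: ",
                   ox$peptide_key[which(mismatch)[1]]),
            class = "kinact_reference_error", call = call)
    }
  }
  panel
}

#' Write a T-loop assay panel table
#' @param panel Panel tibble (see [read_assay_panel()]).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_assay_panel <- function(panel, path) {
  validate_assay_panel(as_tibble(panel))
  readr::write_tsv(dplyr::arrange(as_tibble(panel), .data$peptide_key), path)
  invisible(path)
}

#' Read patient metadata into a cohort design
#'
#' Outcomes follow the neoadjuvant-response convention: pathological complete
#' response (`pCR`), near-complete (`npCR`), and no complete response
#' (`NoPCR`). Patients with pCR are "responders"; npCR and No pCR are
#' "non-responders". Spellings are matched case- and whitespace-insensitively
#' ("No pCR", "no_pcr", "NoPCR" all accepted).
#'
#' @param path Delimited text with columns `patient_id` and `outcome`.
#' @return A tibble with `patient_id`, `outcome` (factor pCR/npCR/NoPCR) and
#'   the derived logical `responder`. Group counts are reported via a message.
#' @export
read_sample_metadata <- function(path) {
  meta <- read_delimited(path)
  if (nrow(meta) == 0) {
    warn("sample metadata file is empty")
    return(tibble(
      patient_id = character(), outcome = factor(levels = outcome_levels()),
      responder = logical()
    ))
  }
  if (!all(c("patient_id", "outcome") %in% names(meta))) {
    abort("sample metadata needs columns 'patient_id' and 'outcome'",
          class = "kinact_format_error")
  }
  design <- cohort_design(meta$patient_id, meta$outcome)
  counts <- table(design$outcome)
  inform(sprintf(
    "cohort: %d patients (%s); %d responders / %d non-responders",
    nrow(design),
    paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
    sum(design$responder), sum(!design$responder)
  ))
  design
}

outcome_levels <- function() c("pCR", "npCR", "NoPCR")

#' Build a cohort design from patient ids and outcome labels
#'
#' @param patient_id Character vector of patient identifiers.
#' @param outcome Outcome labels; normalized to pCR / npCR / NoPCR.
#' @return Tibble with `patient_id`, `outcome`, `responder`.
#' @export
cohort_design <- function(patient_id, outcome) {
  norm <- tolower(gsub("[[:space:]_-]", "", as.character(outcome)))
  mapped <- dplyr::case_when(
    norm == "pcr" ~ "pCR",
    norm == "npcr" ~ "npCR",
    norm %in% c("nopcr", "no") ~ "NoPCR",
    TRUE ~ NA_character_
  )
  if (anyNA(mapped)) {
    bad <- unique(outcome[is.na(mapped)])
    abort(paste0("unknown outcome label(s): ", paste(bad, collapse = ", ")),
          class = "kinact_validation_error")
  }
  if (anyDuplicated(patient_id)) {
    abort("duplicated patient_id in metadata",
          class = "kinact_integrity_error")
  }
  tibble(
    patient_id = as.character(patient_id),
    outcome = factor(mapped, levels = outcome_levels()),
    responder = mapped == "pCR"
  )
}

#' Write / read the per-kinase differential statistics table
#'
#' Column order mirrors the usual clinical reporting layout: activation
#' state, log2 fold change responders vs non-responders, t-test p,
#' patients detected (n and %), AUC and ROC p.
#'
#' @param rows Stats tibble with columns `state_id`, `log2_fc`, `ttest_p`,
#'   `n_detected`, `pct_detected`, `auc`, `roc_p` (extra columns are kept,
#'   appended after the canonical ones).
#' @param path Output path (TSV).
#' @return `path`, invisibly (writer); the stats tibble (reader).
#' @export
write_stats_table <- function(rows, path) {
  rows <- as_tibble(rows)
  canon <- c("state_id", "log2_fc", "ttest_p", "n_detected", "pct_detected",
             "auc", "roc_p")
  missing_cols <- setdiff(canon, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("stats table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "kinact_format_error")
  }
  rows <- rows[c(canon, setdiff(names(rows), canon))]
  readr::write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_stats_table
#' @export
read_stats_table <- function(path) {
  as_tibble(read_delimited(path))
}

#' Write / read a state-by-patient abundance matrix
#'
#' Stored wide: first column `state_id`, one column per patient, `NA` for
#' not-detected cells. In memory the package's canonical form is long
#' (`state_id`, `patient_id`, `log2_abundance`); use [abundance_wide()] /
#' [abundance_long()] to convert.
#'
#' @param abundance Long abundance tibble.
#' @param path Output path (TSV).
#' @return `path`, invisibly (writer); a long abundance tibble (reader).
#' @export
write_abundance_matrix <- function(abundance, path) {
  readr::write_tsv(abundance_wide(abundance), path)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  wide <- read_delimited(path)
  id_col <- names(wide)[1]
  abundance_long(as_tibble(wide), id_col = id_col)
}

#' Convert abundance between long and wide layouts
#'
#' @param abundance Long tibble with an id column, `patient_id` and
#'   `log2_abundance`.
#' @param wide Wide tibble, id column first, one column per patient.
#' @param id_col Name of the id column (`"state_id"` or `"peptide_key"`).
#' @return `abundance_wide()`: wide tibble; `abundance_long()`: long tibble
#'   with not-detected cells dropped.
#' @export
abundance_wide <- function(abundance, id_col = NULL) {
  abundance <- as_tibble(abundance)
  id_col <- id_col %||% intersect(c("state_id", "peptide_key"),
                                  names(abundance))[1]
  tidyr::pivot_wider(
    abundance[c(id_col, "patient_id", "log2_abundance")],
    names_from = "patient_id", values_from = "log2_abundance"
  )
}

#' @rdname abundance_wide
#' @export
abundance_long <- function(wide, id_col = NULL) {
  wide <- as_tibble(wide)
  id_col <- id_col %||% names(wide)[1]
  out <- tidyr::pivot_longer(
    wide, -dplyr::all_of(id_col),
    names_to = "patient_id", values_to = "log2_abundance"
  )
  out[!is.na(out$log2_abundance), ]
}

# Delimiter-sniffing reader: tab-separated canonical, comma accepted.
read_delimited <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "kinact_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (length(header) == 0 || grepl("\t", header)) "\t" else ","
  readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    na = c("", "NA")
  )
}
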