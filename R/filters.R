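#' Transition-level interference filtering
#'
#' Targeted T-loop assays quantify each phosphopeptide from a handful of
#' fragment-ion transitions, with a stable-isotope-labeled ("heavy") internal
#' standard spiked per peptide. Co-eluting interferences corrupt individual
#' light transitions; this cascade removes them in a fixed order:
#'
#' 1. [filter_low_snr()] — drop transitions whose area is below
#'    `snr_min` times the background.
#' 2. [filter_contribution_mismatch()] — drop light transitions whose
#'    relative contribution to the summed peptide signal deviates from the
#'    heavy standard's by more than `contribution_tol`.
#' 3. [filter_sparse_peptides()] — drop peptide/sample groups with fewer
#'    than `min_transitions` surviving light transitions, then peptides
#'    detected in fewer than `min_files` samples.
#' 4. [select_quant_transitions()] — fix, per peptide, the transition set
#'    with a consistent light/heavy ratio, identical across all samples.
#'
#' Each stage returns a subset of its input and is idempotent. Decisions are
#' invariant to rescaling all intensities of a sample by a positive constant.
#'
#' @name interference_filter
NULL

#' Remove transitions below the signal-to-noise threshold
#'
#' A transition is removed iff `area < snr_min * background`. Zero background
#' is treated as noise-free: the transition is kept whenever its area is
#' positive (an absent noise estimate should not discard signal).
#'
#' @param records Validated transition tibble.
#' @param config A [filter_config()].
#' @return Surviving records (same columns, subset of rows).
#' @examples
#' rec <- tibble::tibble(
#'   sample_id = "s1", peptide_key = "PEP", precursor_charge = 2L,
#'   fragment_ion = c("y5", "y6"), label = "light",
#'   area = c(450, 449), background = 150
#' )
#' filter_low_snr(rec, filter_config())$fragment_ion  # "y5" kept
#' @export
filter_low_snr <- function(records, config = filter_config()) {
  records <- as_tibble(records)
  keep <- ifelse(
    records$background == 0,
    records$area > 0,
    records$area >= config$snr_min * records$background
  )
  records[keep, ]
}

#' Remove light transitions with mismatched relative contribution
#'
#' Per (sample, peptide, label) group, each transition's relative
#' contribution is its area divided by the summed area of the group. A light
#' transition is removed iff the absolute difference between its contribution
#' and that of the same fragment ion in the heavy standard exceeds
#' `contribution_tol`, or if the fragment has no surviving heavy counterpart.
#' Heavy records are never removed by this rule.
#'
#' @inheritParams filter_low_snr
#' @return Surviving records.
#' @export
filter_contribution_mismatch <- function(records, config = filter_config()) {
  records <- as_tibble(records)
  contrib <- relative_contribution(records)
  light <- contrib[contrib$label == "light", ]
  heavy <- contrib[contrib$label == "heavy",
                   c("sample_id", "peptide_key", "precursor_charge",
                     "fragment_ion", "contribution")]
  names(heavy)[names(heavy) == "contribution"] <- "contribution_heavy"
  light <- dplyr::left_join(
    light, heavy,
    by = c("sample_id", "peptide_key", "precursor_charge", "fragment_ion")
  )
  drop_light <- is.na(light$contribution_heavy) |
    abs(light$contribution - light$contribution_heavy) > config$contribution_tol
  kept_light <- light[!drop_light, names(records)]
  dplyr::bind_rows(records[records$label == "heavy", ], kept_light)
}

#' Relative contribution of each transition to its peptide's summed signal
#'
#' @param records Transition tibble.
#' @return The records with an added `contribution` column; contributions sum
#'   to 1 within each non-empty (sample, peptide, charge, label) group.
#' @export
relative_contribution <- function(records) {
  records <- as_tibble(records)
  records |>
    group_by(.data$sample_id, .data$peptide_key, .data$precursor_charge,
             .data$label) |>
    mutate(contribution = .data$area / sum(.data$area)) |>
    ungroup()
}

#' Remove sparsely detected peptides
#'
#' A peptide is detected in a sample iff at least `min_transitions` light
#' transitions survive there; all records of undetected (peptide, sample)
#' groups are removed. Peptides detected in fewer than `min_files` samples
#' are then removed entirely.
#'
#' @inheritParams filter_low_snr
#' @return Surviving records. The detection map (one row per retained
#'   peptide/sample) is attached as attribute `"detection"`.
#' @export
filter_sparse_peptides <- function(records, config = filter_config()) {
  records <- as_tibble(records)
  detection <- records |>
    filter(.data$label == "light") |>
    group_by(.data$sample_id, .data$peptide_key) |>
    summarise(n_light = dplyr::n_distinct(.data$fragment_ion),
              .groups = "drop") |>
    filter(.data$n_light >= config$min_transitions)
  n_files <- detection |>
    group_by(.data$peptide_key) |>
    summarise(n_samples = n(), .groups = "drop") |>
    filter(.data$n_samples >= config$min_files)
  detection <- detection[detection$peptide_key %in% n_files$peptide_key, ]
  out <- dplyr::semi_join(records, detection,
                          by = c("sample_id", "peptide_key"))
  attr(out, "detection") <- detection[c("sample_id", "peptide_key")]
  out
}

#' Fix the quantification transition set per peptide
#'
#' For every (peptide, sample) the per-fragment log2(light/heavy) ratio is
#' computed over fragments surviving in both labels; the sample's reference
#' ratio is the median over fragments. A fragment is consistent iff its mean
#' absolute deviation from the reference, across the samples where the
#' peptide is detected, is at most `ratio_consistency_tol` log2 units. The
#' quantification set is the consistent fragments, identical across samples;
#' peptides with fewer than `min_transitions` consistent fragments are
#' excluded from quantification.
#'
#' @inheritParams filter_low_snr
#' @return Tibble with columns `peptide_key`, `fragment_ion` listing the
#'   fixed quantification set.
#' @export
select_quant_transitions <- function(records, config = filter_config()) {
  ratios <- fragment_log_ratios(records)
  if (nrow(ratios) == 0) {
    return(tibble(peptide_key = character(), fragment_ion = character()))
  }
  dev <- ratios |>
    group_by(.data$sample_id, .data$peptide_key) |>
    mutate(deviation = abs(.data$log2_ratio - median(.data$log2_ratio))) |>
    ungroup() |>
    group_by(.data$peptide_key, .data$fragment_ion) |>
    summarise(mad_ratio = mean(.data$deviation), .groups = "drop")
  consistent <- dev[dev$mad_ratio <= config$ratio_consistency_tol, ]
  n_ok <- consistent |>
    group_by(.data$peptide_key) |>
    summarise(n_frag = n(), .groups = "drop") |>
    filter(.data$n_frag >= config$min_transitions)
  out <- consistent[consistent$peptide_key %in% n_ok$peptide_key,
                    c("peptide_key", "fragment_ion")]
  dplyr::arrange(out, .data$peptide_key, .data$fragment_ion)
}

# per-(sample, peptide, fragment) log2 light/heavy ratio; fragments present
# in both labels only
fragment_log_ratios <- function(records) {
  records <- as_tibble(records)
  wide <- tidyr::pivot_wider(
    records[c("sample_id", "peptide_key", "precursor_charge", "fragment_ion",
              "label", "area")],
    names_from = "label", values_from = "area"
  )
  if (!all(c("light", "heavy") %in% names(wide))) {
    return(tibble(sample_id = character(), peptide_key = character(),
                  fragment_ion = character(), log2_ratio = numeric()))
  }
  wide <- wide[!is.na(wide$light) & !is.na(wide$heavy) &
                 wide$light > 0 & wide$heavy > 0, ]
  wide$log2_ratio <- log2(wide$light / wide$heavy)
  wide[c("sample_id", "peptide_key", "fragment_ion", "log2_ratio")]
}

#' Run the full filtering cascade
#'
#' Applies S/N, contribution-mismatch and sparsity filters in order, then
#' selects the quantification transition set.
#'
#' @inheritParams filter_low_snr
#' @return A list with `records` (survivors of the three removal stages,
#'   restricted to peptides with a valid quantification set), `quant_set`
#'   (from [select_quant_transitions()]), `detection` (peptide/sample
#'   detection map), `stage_counts` (named integer vector of record counts
#'   after each stage) and `removed` (records removed, with a `stage`
#'   column).
#' @export
filter_transitions <- function(records, config = filter_config()) {
  records <- validate_transitions(records)
  s0 <- records
  s1 <- filter_low_snr(s0, config)
  s2 <- filter_contribution_mismatch(s1, config)
  s3 <- filter_sparse_peptides(s2, config)
  detection <- attr(s3, "detection")
  quant_set <- select_quant_transitions(s3, config)
  s4 <- s3[s3$peptide_key %in% unique(quant_set$peptide_key), ]
  removed <- dplyr::bind_rows(
    low_snr = dplyr::anti_join(s0, s1, by = transition_key_cols),
    contribution = dplyr::anti_join(s1, s2, by = transition_key_cols),
    sparsity = dplyr::anti_join(s2, s3, by = transition_key_cols),
    no_quant_set = dplyr::anti_join(s3, s4, by = transition_key_cols),
    .id = "stage"
  )
  list(
    records = as_tibble(s4),
    quant_set = quant_set,
    detection = detection[detection$peptide_key %in%
                            unique(quant_set$peptide_key), ],
    stage_counts = c(
      input = nrow(s0), snr = nrow(s1), contribution = nrow(s2),
      sparsity = nrow(s3), quantifiable = nrow(s4)
    ),
    removed = removed
  )
}
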