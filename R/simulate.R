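#' Configuration of the synthetic T-loop cohort generator
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' 32-patient neoadjuvant HER2+ cohort (17 pCR / 6 npCR / 9 No pCR), a
#' targeted panel of 311 T-loop phosphopeptides of which 56 are endogenously
#' detectable, a ~3.6 log10 dynamic range across kinase base abundances,
#' constant per-sample heavy spikes, oxidized satellite peptides at 10-fold
#' lower signal, sporadic interference on individual light transitions, and
#' an S/N-driven detection limit (missingness is informative: low abundance
#' means missing).
#'
#' @param n_patients Integer vector of group sizes, in order pCR, npCR,
#'   NoPCR. Default `c(17, 6, 9)`.
#' @param n_targets Number of targeted peptides (heavy standards). Default
#'   311.
#' @param n_detectable Number of endogenously detectable targets. Default 56.
#' @param dynamic_range Log10 span of detectable base abundances. Default
#'   3.6.
#' @param between_patient_sd Between-patient biological SD of true log2
#'   abundances. Default 1.0.
#' @param heavy_spike_cv CV of the per-(sample, peptide) heavy spike
#'   amount. Default 0.1.
#' @param transition_noise_cv CV of per-transition multiplicative
#'   (lognormal) noise. Default 0.05.
#' @param n_transitions Range of fragment transitions per peptide (sampled
#'   uniformly). Default `c(3, 5)`.
#' @param heavy_base Typical heavy-transition intensity (arbitrary units).
#'   Default 1e5.
#' @param background_level Typical per-transition background intensity.
#'   Default 2000.
#' @param snr_min S/N threshold driving the detection limit (matches the
#'   downstream filter). Default 3.
#' @param interference_rate Fraction of (sample, light transition) cells of
#'   detectable peptides contaminated by co-eluting interference. Default
#'   0.05.
#' @param interference_magnitude Range of the multiplicative boost applied
#'   to contaminated cells. Default `c(2, 10)`.
#' @param oxidation_fraction Fraction of detectable targets carrying an
#'   oxidized satellite peptide at 10-fold lower signal. Default 0.1.
#' @param effects Named numeric vector of injected log2 fold changes
#'   (responders vs non-responders), names being activation-state labels
#'   like `"ERK2 (T185)"`. The default injects the HER2-pathway-like effect
#'   set the pipeline is meant to detect.
#' @param npcr_level Position of the npCR group between NoPCR (0) and pCR
#'   (1) on the injected effect; 0.5 gives the graded intermediate pattern.
#'   Group offsets are rescaled so the responder vs non-responder mean
#'   difference equals the stated effect exactly. Default 0.5.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A list of class `kinact_sim_config`.
#' @export
sim_config <- function(n_patients = c(17L, 6L, 9L),
                       n_targets = 311L,
                       n_detectable = 56L,
                       dynamic_range = 3.6,
                       between_patient_sd = 1.0,
                       heavy_spike_cv = 0.1,
                       transition_noise_cv = 0.05,
                       n_transitions = c(3L, 5L),
                       heavy_base = 1e5,
                       background_level = 2000,
                       snr_min = 3,
                       interference_rate = 0.05,
                       interference_magnitude = c(2, 10),
                       oxidation_fraction = 0.1,
                       effects = default_sim_effects(),
                       npcr_level = 0.5,
                       seed = 1L) {
  stopifnot(
    length(n_patients) == 3, all(n_patients >= 0),
    n_detectable <= n_targets, n_detectable >= 1,
    dynamic_range > 0, between_patient_sd >= 0,
    heavy_spike_cv >= 0, transition_noise_cv >= 0,
    interference_rate >= 0, interference_rate <= 1,
    oxidation_fraction >= 0, oxidation_fraction <= 1,
    npcr_level >= 0, npcr_level <= 1,
    length(interference_magnitude) == 2,
    interference_magnitude[1] >= 1
  )
  structure(
    list(
      n_patients = as.integer(n_patients),
      n_targets = as.integer(n_targets),
      n_detectable = as.integer(n_detectable),
      dynamic_range = dynamic_range,
      between_patient_sd = between_patient_sd,
      heavy_spike_cv = heavy_spike_cv,
      transition_noise_cv = transition_noise_cv,
      n_transitions = as.integer(n_transitions),
      heavy_base = heavy_base,
      background_level = background_level,
      snr_min = snr_min,
      interference_rate = interference_rate,
      interference_magnitude = interference_magnitude,
      oxidation_fraction = oxidation_fraction,
      effects = effects,
      npcr_level = npcr_level,
      seed = as.integer(seed)
    ),
    class = "kinact_sim_config"
  )
}

#' Default injected effect set of the simulator
#'
#' Log2 fold changes (responders vs non-responders) on a HER2-pathway-like
#' set of activation states, including one inverse (FAK-like) marker.
#'
#' @return Named numeric vector.
#' @export
default_sim_effects <- function() {
  c(
    "ERK2 (T185)" = 1.10,
    "CaMK1D (T180)" = 1.15,
    "RSK1 (T573)" = 0.89,
    "p38A (T180)" = 0.78,
    "MARK1 (S219)" = 0.75,
    "ERK1 (T202)" = 0.72,
    "PAK4 (S474)" = 0.57,
    "FAK (Y576)" = -0.64
  )
}

# mean-one lognormal noise with the given CV
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a transition-level T-loop cohort with known ground truth
#'
#' Generates a full transition report (light and heavy rows for every
#' targeted peptide, transition and patient), the matching assay panel and
#' cohort design, and a `SimTruth` ledger from which every record is
#' derivable: heavy area = per-transition base intensity x per-(sample,
#' peptide) spike x lognormal noise; light area = heavy x 2^(true log2
#' abundance) x lognormal noise, times an interference boost on contaminated
#' cells; background is constant per transition. Detection is driven by the
#' S/N rule itself, so low-abundance states drop out informatively.
#'
#' @param config A [sim_config()].
#' @return List of class `kinact_sim` with elements `transitions`, `panel`,
#'   `design`, and `truth` (list: `targets`, `abundance` with true per-
#'   (peptide, patient) log2 values, `effects`, `contaminated` with the
#'   expected contribution shift per contaminated cell, `expected_detection`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = c(4, 2, 2), n_targets = 20,
#'                                   n_detectable = 10,
#'                                   effects = c("ERK2 (T185)" = 1.1),
#'                                   seed = 7))
#' names(sim)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "kinact_sim_config"))
  set.seed(config$seed)

  design <- cohort_design(
    sprintf("P%02d", seq_len(sum(config$n_patients))),
    rep(outcome_levels(), times = config$n_patients)
  )

  targets <- sim_targets(config)
  panel <- targets[c("peptide_key", "kinases", "sites", "is_oxidized",
                     "n_phospho", "paralog_shared", "nonoxidized_partner")]

  transitions_def <- sim_transition_defs(targets, config)

  # true per-(peptide, patient) log2 abundance
  offsets <- effect_offsets(design, targets, config)
  grid <- tidyr::expand_grid(
    peptide_key = targets$peptide_key,
    patient_id = design$patient_id
  )
  grid <- dplyr::left_join(
    grid, targets[c("peptide_key", "base_log2", "is_oxidized",
                    "nonoxidized_partner", "state_id")],
    by = "peptide_key"
  )
  grid <- dplyr::left_join(grid, offsets, by = c("state_id", "patient_id"))
  grid$offset[is.na(grid$offset)] <- 0
  bio <- stats::rnorm(nrow(grid), 0, config$between_patient_sd)
  # oxidized satellites mirror the partner's biological value at 0.1x signal
  key <- paste(grid$peptide_key, grid$patient_id)
  partner_key <- paste(grid$nonoxidized_partner, grid$patient_id)
  bio[grid$is_oxidized] <- bio[match(partner_key[grid$is_oxidized], key)]
  grid$true_log2 <- grid$base_log2 + grid$offset + bio
  truth_abundance <- grid[c("peptide_key", "state_id", "patient_id",
                            "true_log2")]

  # one row per (patient, peptide, fragment): areas for both labels
  cells <- dplyr::inner_join(transitions_def, truth_abundance,
                             by = "peptide_key", relationship = "many-to-many")
  spike <- tidyr::expand_grid(
    peptide_key = targets$peptide_key, patient_id = design$patient_id
  )
  spike$spike <- rlnorm_cv(nrow(spike), config$heavy_spike_cv)
  cells <- dplyr::left_join(cells, spike, by = c("peptide_key", "patient_id"))
  n <- nrow(cells)
  cells$heavy_area <- cells$base_heavy * cells$spike *
    rlnorm_cv(n, config$transition_noise_cv)
  cells$boost <- 1
  contaminated_idx <- which(
    stats::runif(n) < config$interference_rate & cells$detectable
  )
  cells$boost[contaminated_idx] <- stats::runif(
    length(contaminated_idx),
    config$interference_magnitude[1], config$interference_magnitude[2]
  )
  cells$light_area <- cells$heavy_area * 2^cells$true_log2 *
    rlnorm_cv(n, config$transition_noise_cv) * cells$boost

  contaminated <- contribution_shift(cells, contaminated_idx)

  transitions <- dplyr::bind_rows(
    tibble(
      sample_id = cells$patient_id, peptide_key = cells$peptide_key,
      precursor_charge = cells$precursor_charge,
      fragment_ion = cells$fragment_ion, label = "light",
      area = cells$light_area, background = cells$background
    ),
    tibble(
      sample_id = cells$patient_id, peptide_key = cells$peptide_key,
      precursor_charge = cells$precursor_charge,
      fragment_ion = cells$fragment_ion, label = "heavy",
      area = cells$heavy_area, background = cells$background
    )
  )
  transitions <- arrange_transitions(transitions)

  expected_detection <- expected_detection_map(transitions_def,
                                               truth_abundance, config)

  structure(
    list(
      transitions = as_tibble(transitions),
      panel = as_tibble(panel),
      design = design,
      truth = list(
        targets = targets,
        abundance = truth_abundance,
        effects = config$effects,
        contaminated = contaminated,
        expected_detection = expected_detection
      ),
      config = config
    ),
    class = "kinact_sim"
  )
}

# detection limit in log2 abundance units at nominal intensities; with a
# zero background there is no S/N limit and the abundance scale is anchored
# at a fixed reference instead
detection_anchor <- function(config) {
  if (config$background_level > 0) {
    log2(config$snr_min * config$background_level / config$heavy_base)
  } else {
    -4
  }
}

# target table: detectable states first (effect states at the top of the
# abundance range so they are broadly detected), then undetectable targets
sim_targets <- function(config) {
  n_det <- config$n_detectable
  effects <- config$effects
  effect_states <- names(effects)
  if (length(effect_states) > n_det) {
    abort("more effect states than detectable targets",
          class = "kinact_validation_error")
  }
  parsed <- stringr::str_match(effect_states, "^(.*) \\((.*)\\)$")
  if (anyNA(parsed[, 1]) && length(effect_states) > 0) {
    abort("effect names must look like 'KINASE (SITE)'",
          class = "kinact_validation_error")
  }
  n_extra <- n_det - length(effect_states)
  kinases <- c(parsed[, 2], sprintf("STK%03d", seq_len(n_extra)))
  sites <- c(
    gsub(" \\+ ", ";", parsed[, 3]),
    paste0(sample(c("T", "S", "Y"), n_extra, replace = TRUE),
           sample(150:600, n_extra))
  )
  a_star <- detection_anchor(config)
  span <- config$dynamic_range * log2(10)
  # effect states sit comfortably above the detection limit (broadly
  # detected); the remaining detectable states straddle it so that, as in
  # real biopsies, each patient quantifies only part of the detectable panel
  base_log2 <- c(
    stats::runif(length(effect_states), a_star + span / 3, a_star + 2 * span / 3),
    stats::runif(n_extra, a_star - span / 2, a_star + span / 2)
  )
  n_double <- min(4L, n_extra)
  double_idx <- length(effect_states) + seq_len(n_double)
  sites[double_idx] <- paste0(
    sites[double_idx], ";",
    paste0("Y", sample(150:600, n_double))
  )
  n_phospho <- rep(1L, n_det)
  n_phospho[double_idx] <- 2L
  paralog_shared <- stats::runif(n_det) < 0.15
  det <- tibble(
    peptide_key = sprintf("PEP_%s_%s", gsub("[^A-Za-z0-9]", "", kinases),
                          gsub("[^A-Za-z0-9]", "", sites)),
    kinases = kinases, sites = sites,
    is_oxidized = FALSE, n_phospho = n_phospho,
    paralog_shared = paralog_shared,
    nonoxidized_partner = NA_character_,
    base_log2 = base_log2,
    detectable = TRUE
  )
  # oxidized satellites of a subset of detectable targets, 10x lower signal
  n_ox <- round(config$oxidation_fraction * n_det)
  if (n_ox > 0) {
    ox_src <- det[sample.int(n_det, n_ox), ]
    ox <- ox_src
    ox$nonoxidized_partner <- ox_src$peptide_key
    ox$peptide_key <- paste0(ox_src$peptide_key, "_ox")
    ox$is_oxidized <- TRUE
    ox$base_log2 <- ox_src$base_log2 - log2(10)
    det <- dplyr::bind_rows(det, ox)
  }
  n_undet <- config$n_targets - n_det
  undet <- tibble(
    peptide_key = sprintf("PEP_UND%03d", seq_len(n_undet)),
    kinases = sprintf("UDK%03d", seq_len(n_undet)),
    sites = paste0(sample(c("T", "S", "Y"), n_undet, replace = TRUE),
                   sample(150:600, n_undet, replace = TRUE)),
    is_oxidized = FALSE, n_phospho = 1L, paralog_shared = FALSE,
    nonoxidized_partner = NA_character_,
    base_log2 = detection_anchor(config) - stats::runif(n_undet, 6, 10),
    detectable = FALSE
  )
  out <- dplyr::bind_rows(det, undet)
  out$state_id <- state_label(out$kinases, out$sites)
  out
}

# per-peptide fragment transitions with base heavy intensity and background
sim_transition_defs <- function(targets, config) {
  n_tr <- sample(seq(config$n_transitions[1], config$n_transitions[2]),
                 nrow(targets), replace = TRUE)
  def <- tibble(
    peptide_key = rep(targets$peptide_key, n_tr),
    detectable = rep(targets$detectable, n_tr),
    precursor_charge = 2L,
    fragment_ion = unlist(lapply(n_tr, function(k) paste0("y", 2 + seq_len(k))))
  )
  m <- nrow(def)
  def$base_heavy <- config$heavy_base * exp(stats::rnorm(m, 0, 0.5))
  def$background <- config$background_level * rlnorm_cv(m, 0.3)
  def
}

# per-state offsets realising the injected responder-vs-non-responder FC
effect_offsets <- function(design, targets, config) {
  effects <- config$effects
  if (length(effects) == 0) {
    return(tibble(state_id = character(), patient_id = character(),
                  offset = numeric()))
  }
  n_np <- sum(design$outcome == "npCR")
  n_no <- sum(design$outcome == "NoPCR")
  # rescale so mean(pCR) - mean(npCR, NoPCR) equals the stated effect even
  # with the intermediate npCR level
  shrink <- 1 - config$npcr_level * n_np / (n_np + n_no)
  tidyr::expand_grid(
    state_id = names(effects), patient_id = design$patient_id
  ) |>
    dplyr::left_join(design, by = "patient_id") |>
    mutate(
      fc_adj = unname(effects[.data$state_id]) / shrink,
      offset = dplyr::case_when(
        .data$outcome == "pCR" ~ .data$fc_adj,
        .data$outcome == "npCR" ~ config$npcr_level * .data$fc_adj,
        TRUE ~ 0
      )
    ) |>
    select("state_id", "patient_id", "offset")
}

# expected (noise-free) contribution shift for each contaminated cell
contribution_shift <- function(cells, idx) {
  if (length(idx) == 0) {
    return(tibble(sample_id = character(), peptide_key = character(),
                  fragment_ion = character(), boost = numeric(),
                  contribution_shift = numeric()))
  }
  shifts <- cells |>
    group_by(.data$patient_id, .data$peptide_key) |>
    mutate(
      before = .data$base_heavy / sum(.data$base_heavy),
      after = .data$base_heavy * .data$boost /
        sum(.data$base_heavy * .data$boost)
    ) |>
    ungroup()
  out <- shifts[idx, ]
  tibble(
    sample_id = out$patient_id, peptide_key = out$peptide_key,
    fragment_ion = out$fragment_ion, boost = out$boost,
    contribution_shift = out$after - out$before
  )
}

expected_detection_map <- function(transitions_def, truth_abundance, config) {
  cells <- dplyr::inner_join(
    transitions_def, truth_abundance, by = "peptide_key",
    relationship = "many-to-many"
  )
  cells$expected_light <- cells$base_heavy * 2^cells$true_log2
  cells$pass <- cells$expected_light >= config$snr_min * cells$background
  cells |>
    group_by(.data$peptide_key, .data$state_id, .data$patient_id) |>
    summarise(n_pass = sum(.data$pass), .groups = "drop") |>
    mutate(expected_detected = .data$n_pass >= 2L)
}

#' Recovery metrics of a pipeline run against the simulation ground truth
#'
#' Compares estimated responder-vs-non-responder log2 fold changes with the
#' injected effects (bias and RMSE over effect states), and scores the
#' interference filter against the contaminated-transition ledger
#' (sensitivity overall and on strongly contaminated cells with an expected
#' contribution shift of at least 0.5 in absolute value, plus specificity on
#' clean light transitions of detectable peptides).
#'
#' @param sim A `kinact_sim` object.
#' @param abundance State-level abundance tibble from the pipeline.
#' @param removed Removed-record tibble from [filter_transitions()]
#'   (`$removed`); NULL skips filter scoring.
#' @return List with `fc_recovery` (per effect state: true and estimated FC,
#'   bias) and `summary` (one-row tibble: `mean_bias`, `rmse`,
#'   `filter_sensitivity`, `filter_sensitivity_strong`,
#'   `filter_specificity`).
#' @export
truth_report <- function(sim, abundance, removed = NULL) {
  stopifnot(inherits(sim, "kinact_sim"))
  abundance <- as_tibble(abundance)
  design <- sim$design
  effects <- sim$truth$effects
  est <- purrr::map(names(effects), function(s) {
    d <- dplyr::inner_join(
      abundance[abundance$state_id == s,
                c("patient_id", "log2_abundance")],
      design, by = "patient_id"
    )
    fc <- tryCatch(
      responder_test(d$log2_abundance, d$responder)$log2_fc,
      kinact_insufficient_data = function(e) NA_real_
    )
    tibble(state_id = s, true_fc = unname(effects[s]), est_fc = fc)
  }) |>
    dplyr::bind_rows() |>
    mutate(bias = .data$est_fc - .data$true_fc)
  summary <- tibble(
    mean_bias = mean(est$bias, na.rm = TRUE),
    rmse = sqrt(mean(est$bias^2, na.rm = TRUE)),
    filter_sensitivity = NA_real_,
    filter_sensitivity_strong = NA_real_,
    filter_specificity = NA_real_
  )
  contaminated <- sim$truth$contaminated
  if (!is.null(removed) && nrow(contaminated) > 0) {
    removed_light <- removed[removed$label == "light",
                             c("sample_id", "peptide_key", "fragment_ion")]
    hit <- dplyr::semi_join(
      contaminated, removed_light,
      by = c("sample_id", "peptide_key", "fragment_ion")
    )
    strong <- contaminated[abs(contaminated$contribution_shift) >= 0.5, ]
    hit_strong <- dplyr::semi_join(
      strong, removed_light,
      by = c("sample_id", "peptide_key", "fragment_ion")
    )
    detectable_peps <- sim$truth$targets$peptide_key[
      sim$truth$targets$detectable
    ]
    clean_removed <- dplyr::anti_join(
      removed_light[removed_light$peptide_key %in% detectable_peps, ],
      contaminated, by = c("sample_id", "peptide_key", "fragment_ion")
    )
    n_clean <- sum(sim$transitions$label == "light" &
                     sim$transitions$peptide_key %in% detectable_peps) -
      nrow(contaminated)
    summary$filter_sensitivity <- nrow(hit) / nrow(contaminated)
    summary$filter_sensitivity_strong <-
      if (nrow(strong) > 0) nrow(hit_strong) / nrow(strong) else NA_real_
    summary$filter_specificity <- 1 - nrow(clean_removed) / n_clean
  }
  list(fc_recovery = est, summary = summary)
}
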