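test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_cohort(quick_config(seed = 7))
  s2 <- simulate_cohort(quick_config(seed = 7))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_transition_report(s1$transitions, f1)
  write_transition_report(s2$transitions, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical report
  expect_identical(s1$truth$abundance, s2$truth$abundance)
  expect_identical(s1$truth$contaminated, s2$truth$contaminated)

  s3 <- simulate_cohort(quick_config(seed = 8))
  expect_false(identical(s1$transitions$area, s3$transitions$area))
})

test_that("injected effects move group means by exactly the stated FC", {
  cfg <- quick_config(seed = 4, between_patient_sd = 0,
                      effects = c("ERK2 (T185)" = 1.10))
  sim <- simulate_cohort(cfg)
  tr <- dplyr::inner_join(
    sim$truth$abundance[sim$truth$abundance$state_id == "ERK2 (T185)", ],
    sim$design, by = "patient_id"
  )
  expect_equal(
    mean(tr$true_log2[tr$responder]) - mean(tr$true_log2[!tr$responder]),
    1.10, tolerance = 1e-12
  )
  # intermediate npCR level sits between NoPCR and pCR
  mu <- tapply(tr$true_log2, tr$outcome, mean)
  expect_true(mu[["NoPCR"]] < mu[["npCR"]] && mu[["npCR"]] < mu[["pCR"]])
})

test_that("noise-free, interference-free cohorts are recovered exactly", {
  cfg <- quick_config(seed = 5, transition_noise_cv = 0,
                      interference_rate = 0, background_level = 0)
  sim <- simulate_cohort(cfg)
  res <- filter_transitions(sim$transitions, filter_config())
  # zero interference and zero noise: the contribution filter removes nothing
  expect_equal(unname(res$stage_counts["snr"]),
               unname(res$stage_counts["contribution"]))
  ab <- compute_abundance(res$records, res$quant_set)
  joined <- dplyr::inner_join(ab, sim$truth$abundance,
                              by = c("peptide_key", "patient_id"))
  expect_gt(nrow(joined), 0)
  expect_equal(joined$log2_abundance, joined$true_log2, tolerance = 1e-12)
})

test_that("oxidized satellites mirror their partner at 10-fold lower signal", {
  sim <- simulate_cohort(quick_config(seed = 6, oxidation_fraction = 0.3))
  tg <- sim$truth$targets
  ox <- tg[tg$is_oxidized, ]
  expect_gt(nrow(ox), 0)
  partner <- tg[match(ox$nonoxidized_partner, tg$peptide_key), ]
  expect_equal(ox$base_log2, partner$base_log2 - log2(10))
  expect_equal(ox$state_id, partner$state_id)
  # per-patient true values differ by exactly the 10-fold signal penalty
  tr <- sim$truth$abundance
  for (i in seq_len(nrow(ox))) {
    a <- tr$true_log2[tr$peptide_key == ox$peptide_key[i]]
    b <- tr$true_log2[tr$peptide_key == ox$nonoxidized_partner[i]]
    expect_equal(a, b - log2(10), tolerance = 1e-12)
  }
})

test_that("default cohort scale matches the intended study conditions", {
  cfg <- sim_config(seed = 21)
  expect_equal(cfg$n_patients, c(17L, 6L, 9L))
  expect_equal(cfg$n_targets, 311L)
  expect_equal(cfg$n_detectable, 56L)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$design), 32)
  expect_equal(sum(sim$design$responder), 17)
  run <- suppressWarnings(run_pipeline(sim$transitions, sim$panel,
                                       sim$design))
  det <- run$detection$per_patient$n_detected
  # per-patient quantified T-loops fall in the 20-40 band
  expect_true(all(det >= 20 & det <= 40))
  # detectable base abundances span a wide (>3 log10) dynamic range
  span <- diff(range(sim$truth$targets$base_log2[
    sim$truth$targets$detectable & !sim$truth$targets$is_oxidized
  ]))
  expect_gt(span / log2(10), 2.5)
})

test_that("truth_report scores fold-change recovery and the filter", {
  cfg <- quick_config(seed = 9)
  sim <- simulate_cohort(cfg)
  run <- suppressWarnings(run_pipeline(sim$transitions, sim$panel,
                                       sim$design))
  rep <- truth_report(sim, run$abundance, run$filtered$removed)
  expect_equal(rep$fc_recovery$true_fc, unname(cfg$effects))
  expect_true(all(is.finite(rep$fc_recovery$est_fc)))
  expect_lt(rep$summary$rmse, 1.5)
  expect_true(rep$summary$filter_sensitivity >= 0 &&
                rep$summary$filter_sensitivity <= 1)
  expect_true(rep$summary$filter_specificity >= 0 &&
                rep$summary$filter_specificity <= 1)
})

test_that("estimated fold changes are unbiased under the null", {
  null_effects <- stats::setNames(
    rep(0, 20), sprintf("NUL%02d (T%03d)", 1:20, 101:120)
  )
  cfg <- quick_config(seed = 10, n_patients = c(17L, 6L, 9L),
                      between_patient_sd = 0.25, effects = null_effects,
                      n_detectable = 30L, n_targets = 60L)
  sim <- simulate_cohort(cfg)
  run <- suppressWarnings(run_pipeline(sim$transitions, sim$panel,
                                       sim$design))
  rep <- truth_report(sim, run$abundance, run$filtered$removed)
  expect_lt(abs(rep$summary$mean_bias), 0.05)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(interference_rate = 1.5))
  expect_error(sim_config(n_detectable = 100, n_targets = 50))
  expect_error(
    simulate_cohort(quick_config(
      seed = 1, effects = stats::setNames(1, "BADNAME")
    )),
    class = "kinact_validation_error"
  )
})
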