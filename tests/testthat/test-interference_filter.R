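test_that("S/N filter applies the three-times-background rule per record", {
  cfg <- filter_config()
  rec <- tibble::tibble(
    sample_id = "s1", peptide_key = "PEP", precursor_charge = 2L,
    fragment_ion = c("y3", "y4", "y5", "y6"), label = "light",
    area = c(450, 449, 100, 0), background = c(150, 150, 0, 0)
  )
  kept <- filter_low_snr(rec, cfg)
  # 450 >= 3*150 kept (boundary), 449 removed, zero background keeps signal
  expect_setequal(kept$fragment_ion, c("y3", "y5"))
})

test_that("contribution filter removes light transitions mismatching heavy", {
  cfg <- filter_config()
  rec <- toy_peptide(light = c(10, 80, 10), heavy = c(50, 30, 20))
  kept <- filter_contribution_mismatch(rec, cfg)
  # |0.1-0.5| = 0.4 and |0.8-0.3| = 0.5 exceed 0.20; |0.1-0.2| kept
  expect_equal(kept$fragment_ion[kept$label == "light"], "y5")
  expect_equal(sum(kept$label == "heavy"), 3)

  # identical contributions: nothing removed
  same <- toy_peptide(light = c(10, 30, 60), heavy = c(100, 300, 600))
  expect_same_records(filter_contribution_mismatch(same, cfg), same)

  # exactly 20 percentage points is not "more than 20%"
  boundary <- toy_peptide(light = c(70, 30), heavy = c(50, 50))
  expect_same_records(filter_contribution_mismatch(boundary, cfg), boundary)

  # a light fragment with no heavy counterpart is removed
  orphan <- toy_peptide(light = c(50, 50), heavy = c(50, 50))
  orphan <- orphan[!(orphan$label == "heavy" & orphan$fragment_ion == "y4"), ]
  kept2 <- filter_contribution_mismatch(orphan, cfg)
  expect_false(any(kept2$label == "light" & kept2$fragment_ion == "y4"))
})

test_that("sparsity filter enforces min transitions then min files", {
  cfg <- filter_config()
  two_tr <- function(samples) {
    dplyr::bind_rows(lapply(samples, function(s) {
      toy_peptide(light = c(100, 100), heavy = c(100, 100), sample_id = s)
    }))
  }
  kept5 <- filter_sparse_peptides(two_tr(paste0("s", 1:5)), cfg)
  expect_equal(nrow(kept5), 20)  # detected in exactly min_files samples

  kept4 <- filter_sparse_peptides(two_tr(paste0("s", 1:4)), cfg)
  expect_equal(nrow(kept4), 0)

  one_tr <- dplyr::bind_rows(lapply(paste0("s", 1:10), function(s) {
    toy_peptide(light = 100, heavy = 100, sample_id = s)
  }))
  expect_equal(nrow(filter_sparse_peptides(one_tr, cfg)), 0)
})

test_that("quantification transitions need a consistent light/heavy ratio", {
  cfg <- filter_config()
  mk <- function(ratios_by_sample) {
    dplyr::bind_rows(lapply(names(ratios_by_sample), function(s) {
      toy_peptide(light = 100 * 2^ratios_by_sample[[s]],
                  heavy = c(100, 100, 100), sample_id = s)
    }))
  }
  # identical ratios everywhere: all fragments selected
  all_same <- mk(list(s1 = c(1, 1, 1), s2 = c(0, 0, 0), s3 = c(2, 2, 2),
                      s4 = c(1, 1, 1), s5 = c(0, 0, 0)))
  expect_setequal(select_quant_transitions(all_same, cfg)$fragment_ion,
                  c("y3", "y4", "y5"))

  # one fragment 2 log2 units off the per-sample median in half the samples
  half_off <- mk(list(s1 = c(1, 1, 3), s2 = c(1, 1, 1), s3 = c(0, 0, 2),
                      s4 = c(0, 0, 0)))
  qs <- select_quant_transitions(half_off, cfg)
  expect_setequal(qs$fragment_ion, c("y3", "y4"))

  # only one consistent fragment: peptide excluded entirely
  one_ok <- mk(list(s1 = c(0, 2, 4), s2 = c(0, 2, 4), s3 = c(0, 2, 4)))
  expect_equal(nrow(select_quant_transitions(one_ok, cfg)), 0)
})

test_that("stages shrink monotonically, are idempotent and scale-invariant", {
  cfg <- filter_config()
  for (seed in 1:10) {
    rec <- random_transitions(seed)
    s1 <- filter_low_snr(rec, cfg)
    s2 <- filter_contribution_mismatch(s1, cfg)
    s3 <- filter_sparse_peptides(s2, cfg)
    expect_true(all(record_key(s1) %in% record_key(rec)))
    expect_true(all(record_key(s2) %in% record_key(s1)))
    expect_true(all(record_key(s3) %in% record_key(s2)))
    # S/N and sparsity act on frozen per-record / per-group quantities and
    # are idempotent; the contribution stage is single-pass by definition
    # (survivor contributions renormalize), so it is not re-applied here
    expect_same_records(filter_low_snr(s1, cfg), s1)
    expect_same_records(filter_sparse_peptides(s3, cfg), s3)

    # rescaling one sample's intensities by a positive constant changes
    # no decision
    scaled <- rec
    one_sample <- scaled$sample_id == scaled$sample_id[1]
    scaled$area[one_sample] <- scaled$area[one_sample] * 7.3
    scaled$background[one_sample] <- scaled$background[one_sample] * 7.3
    expect_setequal(record_key(filter_low_snr(scaled, cfg)), record_key(s1))
    expect_setequal(
      record_key(filter_contribution_mismatch(filter_low_snr(scaled, cfg),
                                              cfg)),
      record_key(s2)
    )
    sel <- select_quant_transitions(s3, cfg)
    scaled3 <- s3
    one_sample3 <- scaled3$sample_id == scaled3$sample_id[1]
    scaled3$area[one_sample3] <- scaled3$area[one_sample3] * 7.3
    sel_scaled <- select_quant_transitions(scaled3, cfg)
    expect_equal(sel_scaled, sel)
  }
})

test_that("filter_transitions reports monotone stage counts and removals", {
  sim <- simulate_cohort(quick_config(seed = 11))
  res <- filter_transitions(sim$transitions, filter_config())
  counts <- res$stage_counts
  expect_true(all(diff(counts) <= 0))
  expect_equal(unname(counts["input"]), nrow(sim$transitions))
  expect_equal(nrow(res$removed) + unname(counts["quantifiable"]),
               unname(counts["input"]))
  expect_setequal(unique(res$removed$stage),
                  intersect(c("low_snr", "contribution", "sparsity",
                              "no_quant_set"),
                            unique(res$removed$stage)))
})
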