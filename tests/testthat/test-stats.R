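test_that("row z-scoring centers, scales and preserves missingness", {
  m <- tibble::tibble(state_id = c("a", "b", "c"),
                      p1 = c(1, 5, 2), p2 = c(2, 5, NA), p3 = c(3, 5, 4))
  expect_warning(z <- zscore_rows(m), "zero-variance")
  expect_equal(unlist(z[z$state_id == "a", -1], use.names = FALSE),
               c(-1, 0, 1))
  expect_false("b" %in% z$state_id)  # constant row dropped
  cz <- unlist(z[z$state_id == "c", -1], use.names = FALSE)
  expect_true(is.na(cz[2]))
  expect_equal(cz[c(1, 3)], c(-1, 1) / sqrt(2))
})

test_that("pearson matrix is symmetric with unit diagonal", {
  set.seed(2)
  m <- tibble::tibble(
    state_id = c("a", "dup", "neg", "ind1", "ind2"),
    !!!stats::setNames(as.data.frame(rbind(
      x <- stats::rnorm(1000),
      x,
      -x,
      stats::rnorm(1000),
      stats::rnorm(1000)
    )), paste0("p", 1:1000))
  )
  r <- pearson_matrix(m)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(r["a", "dup"], 1)
  expect_equal(r["a", "neg"], -1)
  expect_lt(abs(r["ind1", "ind2"]), 0.1)

  # pairs with under 3 shared observations are masked
  m2 <- tibble::tibble(state_id = c("u", "v"),
                       p1 = c(1, NA), p2 = c(2, 1), p3 = c(3, 2),
                       p4 = c(NA, 3))
  expect_true(is.na(pearson_matrix(m2)["u", "v"]))
})

test_that("one-way ANOVA and Tukey HSD match closed forms", {
  flat <- anova_oneway(rep(c(1, 2), 3),
                       rep(c("pCR", "npCR", "NoPCR"), each = 2))
  expect_equal(flat$f_statistic, 0)
  expect_equal(flat$anova_p, 1)

  # between SS = 6 on 2 df, within SS = 6 on 6 df -> F = 3 exactly
  worked <- anova_oneway(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                         rep(c("pCR", "npCR", "NoPCR"), each = 3))
  expect_equal(worked$f_statistic, 3, tolerance = 1e-12)
  expect_equal(worked$anova_p, stats::pf(3, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  tukey_cols <- grep("^tukey_p_", names(worked), value = TRUE)
  expect_length(tukey_cols, 3)
  expect_true(all(unlist(worked[tukey_cols]) >= 0 &
                    unlist(worked[tukey_cols]) <= 1))

  expect_error(anova_oneway(c(1, 2), c("pCR", "npCR")),
               class = "kinact_insufficient_data")
})

test_that("responder test reproduces the pooled-t closed form", {
  same <- responder_test(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(same$log2_fc, 0)
  expect_equal(same$ttest_p, 1)

  r <- responder_test(c(2, 3, 4, 1, 2, 3),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$log2_fc, 1)
  expect_equal(r$t_statistic, sqrt(1.5), tolerance = 1e-6)  # 1.2247
  expect_equal(r$df, 4)
  expect_equal(r$ttest_p, 2 * stats::pt(-sqrt(1.5), 4), tolerance = 1e-12)

  w <- responder_test(c(2, 3, 4, 1, 2, 3),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                      var_equal = FALSE)
  expect_equal(w$log2_fc, 1)

  expect_error(responder_test(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               class = "kinact_insufficient_data")
})

test_that("ROC AUC matches pair enumeration, ties and orientation", {
  perfect <- roc_auc(c(1, 2, 3, 4, 5, 6),
                     c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)

  ties <- roc_auc(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(ties$auc, 0.5)
  expect_equal(ties$p_value, 1)

  # {1,2} negatives vs {2,3} positives: 3.5 of 4 pairs
  four <- roc_auc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(four$auc, 3.5 / 4)

  # inverse marker scored with direction = "low"
  inv <- roc_auc(c(5, 4, 1, 2), c(FALSE, FALSE, TRUE, TRUE),
                 direction = "low")
  expect_equal(inv$auc, 1)

  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)),
               class = "kinact_undefined_auc")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  for (i in 1:20) {
    scores <- stats::rnorm(30)
    labels <- stats::runif(30) < 0.4
    if (length(unique(labels)) < 2) next
    a0 <- roc_auc(scores, labels)$auc
    expect_equal(roc_auc(exp(scores), labels)$auc, a0)
    expect_equal(roc_auc(stats::qlogis(stats::plogis(scores)), labels)$auc,
                 a0, tolerance = 1e-12)
  }
})

test_that("ROC analysis cross-checks against an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    scores <- round(stats::rnorm(40), 1)  # rounding forces ties
    labels <- stats::runif(40) < 0.5
    if (length(unique(labels)) < 2) next
    ours <- roc_auc(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      direction = "<", quiet = TRUE
    )))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("logistic panel fitting recovers closed-form coefficients", {
  design <- cohort_design(sprintf("p%02d", 1:16),
                          c(rep("pCR", 12), rep("NoPCR", 4)))
  fit0 <- fit_logistic(tibble::tibble(
    state_id = character(), patient_id = character(),
    log2_abundance = numeric()
  ), design, states = character())
  expect_equal(unname(fit0$coefficients[1]), log(3), tolerance = 1e-8)

  # 2x2 table: x=0 1/4 positive, x=1 3/4 positive -> slope = log 9
  design2 <- cohort_design(
    sprintf("q%02d", 1:8),
    c("NoPCR", "NoPCR", "NoPCR", "pCR", "pCR", "pCR", "pCR", "NoPCR")
  )
  ab2 <- tibble::tibble(
    state_id = "X (T1)", patient_id = design2$patient_id,
    log2_abundance = c(0, 0, 0, 0, 1, 1, 1, 1)
  )
  fit2 <- fit_logistic(ab2, design2, "X (T1)")
  expect_equal(unname(fit2$coefficients["X (T1)"]), log(9),
               tolerance = 1e-6)
  expect_true(fit2$converged)

  # perfectly separable predictor flagged
  ab3 <- ab2
  ab3$log2_abundance <- as.numeric(design2$responder)
  fit3 <- fit_logistic(ab3, design2, "X (T1)")
  expect_true(fit3$separation)
  expect_false(fit3$converged)
  expect_equal(fit3$auc, 1)

  expect_equal(tidy(fit2)$term[1], "(Intercept)")
  expect_equal(glance(fit2)$n_complete, 8)
})

test_that("adding a predictor never increases logistic deviance", {
  set.seed(17)
  for (i in 1:10) {
    n <- 30
    design <- cohort_design(
      sprintf("p%02d", 1:n),
      ifelse(stats::runif(n) < 0.5, "pCR", "NoPCR")
    )
    if (length(unique(design$responder)) < 2) next
    ab <- dplyr::bind_rows(
      tibble::tibble(state_id = "A (T1)", patient_id = design$patient_id,
                     log2_abundance = stats::rnorm(n)),
      tibble::tibble(state_id = "B (S2)", patient_id = design$patient_id,
                     log2_abundance = stats::rnorm(n))
    )
    d1 <- fit_logistic(ab, design, "A (T1)")$deviance
    d2 <- fit_logistic(ab, design, c("A (T1)", "B (S2)"))$deviance
    expect_lte(d2, d1 + 1e-8)
  }
})

test_that("panel rules reproduce the published six- and four-state panels", {
  stats_tbl <- reference_kinase_stats()
  expect_setequal(
    select_panel(stats_tbl, "six_kinase"),
    c("RSK1 (T573)", "CaMK1D (T180)", "p38A (T180)", "ERK1 (T202)",
      "ERK2 (T185)", "MARK1 (S219)")
  )
  expect_setequal(
    select_panel(stats_tbl, "four_kinase"),
    c("RSK1 (T573)", "ERK1 (T202)", "ERK2 (T185)", "PAK4 (S474)")
  )
  expect_warning(sel <- select_panel(stats_tbl[0, ], "six_kinase"),
                 "selected no states")
  expect_length(sel, 0)
})

test_that("hierarchical clustering orders by Euclidean similarity", {
  z <- tibble::tibble(
    state_id = c("a", "b"),
    c1 = c(0, 1), c2 = c(0, 1), c3 = c(5, 6), c4 = c(0.1, 1.1)
  )
  cl <- hierarchical_cluster(z)
  # identical-profile columns merge first, the outlier joins last
  first_merge <- cl$col_tree$merge[1, ]
  expect_setequal(colnames(cl$z)[-first_merge], c("c1", "c2"))
  expect_equal(cl$col_tree$height[1], 0)
  groups <- stats::cutree(cl$col_tree, k = 2)
  expect_equal(unname(groups[c("c1", "c2", "c4")]), rep(1, 3))
  expect_equal(unname(groups["c3"]), 2)
  expect_setequal(cl$col_order, paste0("c", 1:4))
  expect_setequal(cl$row_order, c("a", "b"))
})

test_that("clustering separates simulated outcome groups", {
  set.seed(23)
  hits <- 0
  n_runs <- 20
  for (i in seq_len(n_runs)) {
    truth <- rep(c(1, 2), each = 6)
    m <- matrix(stats::rnorm(10 * 12), nrow = 10)
    m[, truth == 2] <- m[, truth == 2] + 2  # 2-sd group effect
    z <- zscore_rows(dplyr::bind_cols(
      tibble::tibble(state_id = paste0("s", 1:10)),
      tibble::as_tibble(as.data.frame(m), .name_repair = ~ paste0("p", 1:12))
    ))
    cl <- hierarchical_cluster(z)
    cut <- stats::cutree(cl$col_tree, k = 2)
    hits <- hits + as.integer(all(table(cut, truth) %in% c(0, 6)))
  }
  expect_gte(hits, 0.9 * n_runs)
})

test_that("diff_stats assembles the per-state reporting table", {
  sim <- simulate_cohort(quick_config(seed = 19))
  run <- suppressWarnings(run_pipeline(sim$transitions, sim$panel,
                                       sim$design))
  st <- run$stats
  expect_true(all(c("state_id", "log2_fc", "ttest_p", "anova_p",
                    "n_detected", "pct_detected", "auc", "roc_p") %in%
                    names(st)))
  ok <- !is.na(st$auc)
  expect_true(all(st$auc[ok] >= 0 & st$auc[ok] <= 1))
  expect_true(all(st$n_detected <= nrow(sim$design)))
  expect_equal(st$pct_detected,
               100 * st$n_detected / nrow(sim$design))
  # ROC orientation follows the fold-change sign
  dat <- dplyr::inner_join(run$abundance, sim$design, by = "patient_id")
  for (s in st$state_id[ok][1:5]) {
    d <- dat[dat$state_id == s, ]
    fc <- st$log2_fc[st$state_id == s]
    manual <- roc_auc(d$log2_abundance, d$responder,
                      direction = if (fc >= 0) "high" else "low")$auc
    expect_equal(st$auc[st$state_id == s], manual)
  }

  bh <- suppressWarnings(
    diff_stats(run$abundance, sim$design, p_adjust = "BH")
  )
  expect_true(all(bh$ttest_p_adj >= bh$ttest_p, na.rm = TRUE))
})
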