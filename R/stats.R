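#' Z-score a wide abundance table by row
#'
#' Each activation state (row) is centered and scaled by its observed mean
#' and sample standard deviation; missing cells stay missing. Rows with
#' fewer than 2 observed values or zero variance are dropped with a warning.
#'
#' @param wide Wide tibble: id column first, one numeric column per patient.
#' @return Wide tibble of z-scores, same layout.
#' @examples
#' m <- tibble::tibble(state_id = "a", p1 = 1, p2 = 2, p3 = 3)
#' zscore_rows(m)  # -1, 0, 1
#' @export
zscore_rows <- function(wide) {
  wide <- as_tibble(wide)
  id_col <- names(wide)[1]
  vals <- as.matrix(wide[-1])
  mu <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1, sd, na.rm = TRUE)
  n_obs <- rowSums(!is.na(vals))
  bad <- n_obs < 2 | is.na(sdv) | sdv == 0
  if (any(bad)) {
    warn(sprintf("dropped %d zero-variance or under-observed row(s): %s",
                 sum(bad),
                 paste(utils::head(wide[[id_col]][bad], 5), collapse = ", ")))
  }
  z <- (vals[!bad, , drop = FALSE] - mu[!bad]) / sdv[!bad]
  dplyr::bind_cols(wide[!bad, 1], as_tibble(z))
}

#' State-by-state Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlation between activation-state profiles;
#' pairs sharing fewer than `min_obs` patients are set missing.
#'
#' @param wide Wide abundance tibble (id column first).
#' @param min_obs Minimum shared observations per pair. Default 3.
#' @return Symmetric correlation matrix with unit diagonal, dimnames from
#'   the id column.
#' @export
pearson_matrix <- function(wide, min_obs = 3L) {
  wide <- as_tibble(wide)
  vals <- t(as.matrix(wide[-1]))
  colnames(vals) <- wide[[1]]
  r <- suppressWarnings(cor(vals, use = "pairwise.complete.obs"))
  obs <- crossprod(!is.na(vals))
  r[obs < min_obs] <- NA_real_
  diag(r) <- 1
  r
}

#' One-way ANOVA with Tukey HSD across the three outcome groups
#'
#' Classical fixed-effects one-way ANOVA (via [stats::aov()]) followed by
#' Tukey's honestly-significant-difference pairwise comparisons
#' ([stats::TukeyHSD()]), complete-case per state.
#'
#' @param values Numeric abundances, one per patient with the state detected.
#' @param groups Outcome labels, same length (2 or 3 levels present).
#' @param min_per_group Minimum observations required in at least two
#'   groups. Default 2.
#' @return One-row tibble: `f_statistic`, `anova_p`, and one
#'   `tukey_p_<a>_vs_<b>` column per group pair (NA when Tukey is not
#'   defined).
#' @examples
#' anova_oneway(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'              rep(c("pCR", "npCR", "NoPCR"), each = 3))
#' @export
anova_oneway <- function(values, groups, min_per_group = 2L) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  sizes <- table(groups)
  if (length(sizes) < 2 || sum(sizes >= min_per_group) < 2) {
    abort("need at least two groups with enough observations",
          class = "kinact_insufficient_data")
  }
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  out <- tibble(
    f_statistic = tab[["F value"]][1],
    anova_p = tab[["Pr(>F)"]][1]
  )
  tk <- tryCatch(TukeyHSD(fit)$groups, error = function(e) NULL)
  if (!is.null(tk)) {
    p <- tk[, "p adj"]
    names(p) <- paste0("tukey_p_", gsub("-", "_vs_", rownames(tk)))
    out <- dplyr::bind_cols(out, as_tibble(as.list(p)))
  }
  out
}

#' Responder vs non-responder fold change and t-test
#'
#' Log2 fold change is mean(responders) - mean(non-responders) on the
#' already-log2 abundances; the two-sided p-value comes from Student's
#' pooled-variance t-test by default (Welch via `var_equal = FALSE`).
#'
#' @param values Numeric log2 abundances (complete-case for this state).
#' @param responder Logical, same length: TRUE for responders.
#' @param var_equal Pooled-variance Student test when TRUE (default);
#'   Welch otherwise.
#' @param min_per_group Minimum patients per class. Default 2.
#' @return One-row tibble: `log2_fc`, `t_statistic`, `df`, `ttest_p`,
#'   `n_responder`, `n_nonresponder`.
#' @examples
#' responder_test(c(2, 3, 4, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
responder_test <- function(values, responder, var_equal = TRUE,
                           min_per_group = 2L) {
  keep <- !is.na(values) & !is.na(responder)
  values <- values[keep]
  responder <- responder[keep]
  n1 <- sum(responder)
  n0 <- sum(!responder)
  if (n1 < min_per_group || n0 < min_per_group) {
    abort(sprintf("too few patients per class (%d responders, %d non)",
                  n1, n0),
          class = "kinact_insufficient_data")
  }
  tt <- stats::t.test(values[responder], values[!responder],
                      var.equal = var_equal)
  tibble(
    log2_fc = mean(values[responder]) - mean(values[!responder]),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    ttest_p = tt$p.value,
    n_responder = n1,
    n_nonresponder = n0
  )
}

#' Per-state differential statistics table
#'
#' Runs, complete-case per activation state: responder-vs-non-responder
#' log2 fold change and t-test, one-way ANOVA across the three outcome
#' groups with Tukey HSD, detection counts, and ROC analysis oriented by
#' the sign of the fold change (see [roc_auc()]). States failing a
#' minimum-group-size check for a given test get NA for that test.
#'
#' @param abundance State-level long abundance tibble.
#' @param design Cohort design ([cohort_design()]).
#' @param var_equal Passed to [responder_test()].
#' @param min_per_group Minimum patients per class for testing. Default 2.
#' @param p_adjust Multiple-testing correction for the t-test and ANOVA
#'   p-values: `"none"` (default) or `"BH"`; adjusted values are reported
#'   in additional columns, raw p-values are never overwritten.
#' @return Stats tibble, one row per state, ordered by `ttest_p`:
#'   `state_id`, `log2_fc`, `ttest_p`, `anova_p`, Tukey columns,
#'   `n_detected`, `pct_detected`, `auc`, `roc_p` (+ `ttest_p_adj`,
#'   `anova_p_adj` when `p_adjust = "BH"`).
#' @export
diff_stats <- function(abundance, design, var_equal = TRUE,
                       min_per_group = 2L, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  abundance <- as_tibble(abundance)
  design <- as_tibble(design)
  dat <- dplyr::inner_join(
    abundance[c("state_id", "patient_id", "log2_abundance")],
    design, by = "patient_id"
  )
  n_cohort <- nrow(design)
  rows <- dat |>
    dplyr::group_split(.data$state_id) |>
    purrr::map(function(d) {
      base <- tibble(
        state_id = d$state_id[1],
        n_detected = nrow(d),
        pct_detected = 100 * nrow(d) / n_cohort
      )
      rt <- tryCatch(
        responder_test(d$log2_abundance, d$responder, var_equal = var_equal,
                       min_per_group = min_per_group),
        kinact_insufficient_data = function(e) NULL
      )
      an <- tryCatch(
        anova_oneway(d$log2_abundance, d$outcome,
                     min_per_group = min_per_group),
        kinact_insufficient_data = function(e) NULL
      )
      rc <- NULL
      if (!is.null(rt)) {
        rc <- tryCatch(
          roc_auc(d$log2_abundance, d$responder,
                  direction = if (rt$log2_fc >= 0) "high" else "low"),
          kinact_undefined_auc = function(e) NULL
        )
      }
      dplyr::bind_cols(
        base,
        if (is.null(rt)) tibble(log2_fc = NA_real_, ttest_p = NA_real_)
        else rt[c("log2_fc", "ttest_p")],
        if (is.null(an)) tibble(anova_p = NA_real_)
        else an[setdiff(names(an), "f_statistic")],
        if (is.null(rc)) tibble(auc = NA_real_, roc_p = NA_real_)
        else tibble(auc = rc$auc, roc_p = rc$p_value)
      )
    }) |>
    dplyr::bind_rows()
  if (p_adjust == "BH") {
    rows$ttest_p_adj <- stats::p.adjust(rows$ttest_p, method = "BH")
    rows$anova_p_adj <- stats::p.adjust(rows$anova_p, method = "BH")
  }
  canon <- c("state_id", "log2_fc", "ttest_p", "n_detected", "pct_detected",
             "auc", "roc_p")
  rows <- rows[c(canon, setdiff(names(rows), canon))]
  dplyr::arrange(rows, .data$ttest_p)
}
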