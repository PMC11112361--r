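#' Select a multi-kinase predictive panel from the stats table
#'
#' Two published-style rules over the per-state statistics:
#' * `six_kinase`: t-test p < 0.05 AND linear fold change `2^|log2_fc|` >
#'   1.5 AND detected in at least 80% of patients.
#' * `four_kinase`: t-test p < 0.05 AND detected in 100% of patients.
#'
#' @param stats Stats tibble with `state_id`, `log2_fc`, `ttest_p`,
#'   `pct_detected` (see [diff_stats()] / [read_stats_table()]).
#' @param rule `"six_kinase"` or `"four_kinase"`.
#' @return Character vector of selected `state_id`s (possibly empty, with a
#'   warning).
#' @examples
#' select_panel(reference_kinase_stats(), "four_kinase")
#' @export
select_panel <- function(stats, rule = c("six_kinase", "four_kinase")) {
  rule <- match.arg(rule)
  stats <- as_tibble(stats)
  sig <- !is.na(stats$ttest_p) & stats$ttest_p < 0.05
  sel <- if (rule == "six_kinase") {
    sig & 2^abs(stats$log2_fc) > 1.5 & stats$pct_detected >= 80
  } else {
    sig & stats$pct_detected == 100
  }
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) warn(paste0("rule '", rule, "' selected no states"))
  stats$state_id[sel]
}

#' Fit a multiple-logistic-regression kinase panel
#'
#' Maximum-likelihood logistic regression of responder status on the panel
#' states' log2 abundances, fitted by iteratively reweighted least squares,
#' restricted to patients with every panel state detected (complete-case; no
#' imputation). Zero-variance predictors are dropped with a warning.
#' Complete separation (diverging coefficients / degenerate fitted
#' probabilities) is detected and flagged as non-converged. The panel AUC is
#' computed from the fitted probabilities via [roc_auc()].
#'
#' @param abundance State-level long abundance tibble.
#' @param design Cohort design ([cohort_design()]).
#' @param states Character vector of panel `state_id`s (e.g. from
#'   [select_panel()]); empty selects an intercept-only model.
#' @return Object of class `kinact_panel_fit`: list with `states`,
#'   `coefficients` (named, intercept first), `fitted` (tibble patient_id,
#'   responder, prob), `roc` (`kinact_roc` on fitted probabilities),
#'   `auc`, `converged`, `separation`, `n_complete`, `deviance`.
#' @export
fit_logistic <- function(abundance, design, states) {
  abundance <- as_tibble(abundance)
  design <- as_tibble(design)
  wide <- tidyr::pivot_wider(
    abundance[abundance$state_id %in% states,
              c("state_id", "patient_id", "log2_abundance")],
    names_from = "state_id", values_from = "log2_abundance"
  )
  dat <- dplyr::left_join(design[c("patient_id", "responder")], wide,
                          by = "patient_id")
  cc <- complete.cases(dat)
  if (!any(cc)) {
    limiting <- states[colSums(is.na(dat[, states, drop = FALSE])) > 0]
    abort(paste0("no patients with all panel states detected; limiting: ",
                 paste(limiting, collapse = ", ")),
          class = "kinact_insufficient_data")
  }
  dat <- dat[cc, ]
  if (length(unique(dat$responder)) < 2) {
    abort("need both classes among complete-case patients",
          class = "kinact_insufficient_data")
  }
  keep_states <- states
  if (length(states) > 0) {
    zero_var <- vapply(dat[states], function(x) sd(x) == 0, logical(1))
    if (any(zero_var)) {
      warn(paste0("dropping zero-variance predictor(s): ",
                  paste(states[zero_var], collapse = ", ")))
      keep_states <- states[!zero_var]
    }
  }
  x <- dat[keep_states]
  names(x) <- make.names(keep_states)
  fit_dat <- dplyr::bind_cols(tibble(.y = as.integer(dat$responder)), x)
  fml <- if (length(keep_states) == 0) {
    .y ~ 1
  } else {
    stats::as.formula(paste(".y ~", paste(names(x), collapse = " + ")))
  }
  fit <- suppressWarnings(
    glm(fml, family = binomial(), data = fit_dat,
        control = list(epsilon = 1e-8, maxit = 100))
  )
  co <- coef(fit)
  probs <- unname(fitted(fit))
  # near-degenerate fitted probabilities with huge coefficients = separation
  separation <- length(keep_states) > 0 &&
    (any(abs(co[-1]) > 15) || all(probs < 1e-6 | probs > 1 - 1e-6))
  converged <- fit$converged && !separation
  roc <- roc_auc(probs, dat$responder)
  names(co) <- c("(Intercept)", keep_states)[seq_along(co)]
  structure(
    list(
      states = keep_states,
      coefficients = co,
      fitted = tibble(patient_id = dat$patient_id,
                      responder = dat$responder, prob = probs),
      roc = roc,
      auc = roc$auc,
      converged = converged,
      separation = separation,
      n_complete = nrow(dat),
      deviance = fit$deviance
    ),
    class = "kinact_panel_fit"
  )
}

#' @export
print.kinact_panel_fit <- function(x, ...) {
  cat(sprintf(
    "<kinact panel fit>  %d state(s), n = %d, AUC = %.3f%s\n",
    length(x$states), x$n_complete, x$auc,
    if (!x$converged) " [NOT converged / separation]" else ""
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted kinase panel
#' @param x A `kinact_panel_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (log-odds scale).
#' @method tidy kinact_panel_fit
#' @export
tidy.kinact_panel_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' One-row summary of a fitted kinase panel
#' @param x A `kinact_panel_fit`.
#' @param ... Unused.
#' @return Tibble with `n_states`, `n_complete`, `auc`, `roc_p`,
#'   `deviance`, `converged`, `separation`.
#' @method glance kinact_panel_fit
#' @export
glance.kinact_panel_fit <- function(x, ...) {
  tibble(
    n_states = length(x$states), n_complete = x$n_complete,
    auc = x$auc, roc_p = x$roc$p_value, deviance = x$deviance,
    converged = x$converged, separation = x$separation
  )
}

#' Tidy the points of a ROC curve
#' @param x A `kinact_roc`.
#' @param ... Unused.
#' @return Tibble of `threshold`, `fpr`, `tpr`.
#' @method tidy kinact_roc
#' @export
tidy.kinact_roc <- function(x, ...) x$curve

#' One-row summary of a ROC analysis
#' @param x A `kinact_roc`.
#' @param ... Unused.
#' @return Tibble with `auc`, `se`, `p_value`, `n_pos`, `n_neg`,
#'   `direction`.
#' @method glance kinact_roc
#' @export
glance.kinact_roc <- function(x, ...) {
  tibble(auc = x$auc, se = x$se, p_value = x$p_value,
         n_pos = x$n_pos, n_neg = x$n_neg, direction = x$direction)
}
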