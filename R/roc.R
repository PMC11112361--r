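#' ROC curve and AUC for a single predictor
#'
#' The AUC is computed in its Mann-Whitney formulation: the probability that
#' a randomly chosen positive (responder) scores above a randomly chosen
#' negative, ties counted one half. The p-value is a two-sided z-test of the
#' AUC against 0.5 using the Hanley-McNeil standard error.
#'
#' Orientation: with `direction = "high"` (default) higher scores indicate
#' the positive class; `"low"` negates the scores first (used for states
#' whose abundance is lower in responders, e.g. FAK-like inverse markers);
#' `"auto"` picks whichever direction gives AUC >= 0.5.
#'
#' @param scores Numeric predictor (e.g. log2 abundances).
#' @param labels Logical (TRUE = positive class) or coercible to logical.
#' @param direction `"high"`, `"low"` or `"auto"`.
#' @return Object of class `kinact_roc`: list with `auc`, `se`, `p_value`,
#'   `direction`, `n_pos`, `n_neg` and `curve` (tibble of threshold, fpr,
#'   tpr points including the (0,0) and (1,1) endpoints).
#' @examples
#' roc_auc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))$auc  # 0.875
#' @export
roc_auc <- function(scores, labels, direction = c("high", "low", "auto")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: need both classes among scored patients",
          class = "kinact_undefined_auc")
  }
  if (direction == "low") scores <- -scores
  auc <- mann_whitney_auc(scores, labels)
  if (direction == "auto" && auc < 0.5) {
    scores <- -scores
    auc <- mann_whitney_auc(scores, labels)
    direction <- "low"
  } else if (direction == "auto") {
    direction <- "high"
  }
  # Hanley & McNeil (1982) standard error of the empirical AUC
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  p_value <- if (se == 0) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * pnorm(-abs(auc - 0.5) / se)
  }
  structure(
    list(
      auc = auc, se = se, p_value = p_value, direction = direction,
      n_pos = n_pos, n_neg = n_neg,
      curve = roc_curve_points(scores, labels)
    ),
    class = "kinact_roc"
  )
}

# ties counted 0.5 via midranks
mann_whitney_auc <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

roc_curve_points <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map(thr, function(t) {
    tibble(
      threshold = t,
      fpr = sum(scores[!labels] >= t) / sum(!labels),
      tpr = sum(scores[labels] >= t) / sum(labels)
    )
  })
  dplyr::bind_rows(
    tibble(threshold = Inf, fpr = 0, tpr = 0),
    dplyr::bind_rows(pts)
  )
}

#' @export
print.kinact_roc <- function(x, ...) {
  cat(sprintf(
    "<kinact ROC>  AUC = %.3f (SE %.3f), p = %.4g, %d pos / %d neg, direction = %s\n",
    x$auc, x$se, x$p_value, x$n_pos, x$n_neg, x$direction
  ))
  invisible(x)
}

#' Trapezoidal area under an empirical ROC curve
#'
#' Companion check to the Mann-Whitney AUC: integrates the `curve`
#' component of a [roc_auc()] result with the trapezoid rule. The two
#' agree exactly (ties half-counted) on any score set.
#'
#' @param roc A `kinact_roc` object.
#' @return Numeric area.
#' @export
trapezoid_auc <- function(roc) {
  cv <- dplyr::arrange(roc$curve, .data$fpr, .data$tpr)
  sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) + utils::tail(cv$tpr, -1)) / 2)
}
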