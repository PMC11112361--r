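#' Hierarchical clustering of the z-scored abundance matrix
#'
#' Agglomerative clustering of activation states (rows) and patients
#' (columns) on Euclidean distance, complete linkage by default (average
#' and Ward selectable). Distances between profiles with missing cells are
#' computed over the shared observed dimensions and rescaled by
#' `sqrt(total dims / observed dims)` (the convention of [stats::dist()]).
#' Pairs sharing no observation are placed at the maximum finite distance,
#' with a warning. Tie-breaking is deterministic in input order.
#'
#' @param z Wide z-scored tibble (id column first), e.g. from
#'   [zscore_rows()].
#' @param linkage `"complete"` (default), `"average"` or `"ward"`
#'   (ward.D2).
#' @return Object of class `kinact_cluster`: list with `row_order` and
#'   `col_order` (label permutations), `row_tree` / `col_tree` (hclust),
#'   and `z` (the numeric matrix clustered).
#' @export
hierarchical_cluster <- function(z, linkage = c("complete", "average",
                                                "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  z <- as_tibble(z)
  if (nrow(z) < 2 || ncol(z) < 3) {
    abort("need at least 2 rows and 2 columns to cluster",
          class = "kinact_insufficient_data")
  }
  m <- as.matrix(z[-1])
  rownames(m) <- z[[1]]
  row_tree <- hclust(euclid_dist_na(m), method = method)
  col_tree <- hclust(euclid_dist_na(t(m)), method = method)
  structure(
    list(
      row_order = rownames(m)[row_tree$order],
      col_order = colnames(m)[col_tree$order],
      row_tree = row_tree,
      col_tree = col_tree,
      z = m
    ),
    class = "kinact_cluster"
  )
}

# stats::dist already rescales by p/n_observed; patch all-missing pairs
euclid_dist_na <- function(m) {
  d <- dist(m, method = "euclidean")
  if (anyNA(d)) {
    warn(sprintf(
      "%d item pair(s) share no observed dimension; placed at max distance",
      sum(is.na(d))
    ))
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- mx * 1.01
  }
  d
}

#' @export
print.kinact_cluster <- function(x, ...) {
  cat(sprintf("<kinact cluster>  %d states x %d patients\n",
              nrow(x$z), ncol(x$z)))
  cat("  column order:", paste(utils::head(x$col_order, 8), collapse = ", "),
      if (length(x$col_order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Heatmap of a clustering result
#'
#' ggplot2 tile heatmap with rows and columns in dendrogram order.
#'
#' @param object A `kinact_cluster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinact_cluster
#' @export
autoplot.kinact_cluster <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(object$z, stringsAsFactors = FALSE))
  names(df) <- c("state_id", "patient_id", "z")
  df$state_id <- factor(df$state_id, levels = rev(object$row_order))
  df$patient_id <- factor(df$patient_id, levels = object$col_order)
  ggplot2::ggplot(df, ggplot2::aes(.data$patient_id, .data$state_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve plot
#'
#' @param object A `kinact_roc`.
#' @param ... Unused.
#' @return A ggplot object (step curve with the chance diagonal).
#' @method autoplot kinact_roc
#' @export
autoplot.kinact_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#B2182B") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f (p = %.3g)", object$auc, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Per-patient detection-count plot
#'
#' Bar chart of the number of activation states quantified per patient,
#' grouped by treatment outcome.
#'
#' @param summary Output of [detection_summary()].
#' @return A ggplot object.
#' @export
plot_detection <- function(summary) {
  pp <- summary$per_patient
  pp$patient_id <- factor(pp$patient_id,
                          levels = pp$patient_id[order(pp$outcome,
                                                       -pp$n_detected)])
  ggplot2::ggplot(pp, ggplot2::aes(.data$patient_id, .data$n_detected,
                                   fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "T-loops quantified", fill = "Outcome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
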