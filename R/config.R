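#' Interference-filter configuration
#'
#' Bundles the thresholds of the transition-level filtering cascade:
#' signal-to-noise, light/heavy relative-contribution mismatch, minimum
#' transitions per detected peptide, minimum files per retained peptide,
#' and the log2 ratio-consistency tolerance used when fixing the
#' quantification transition set.
#'
#' @param snr_min Signal-to-noise threshold: a transition is removed when
#'   its area is below `snr_min` times its background. Default 3.
#' @param contribution_tol Maximum absolute difference (fraction, 0-1)
#'   between a light transition's relative contribution and that of its
#'   heavy counterpart. Default 0.20.
#' @param min_transitions Minimum surviving light transitions for a peptide
#'   to count as detected in a sample, and minimum consistent transitions
#'   for quantification. Default 2.
#' @param min_files Minimum number of samples a peptide must be detected in
#'   to be retained. Default 5.
#' @param ratio_consistency_tol Maximum mean absolute deviation (log2 units)
#'   of a fragment's light/heavy ratio from the per-sample median ratio for
#'   the fragment to enter the quantification set. Default 0.5.
#' @return A list of class `kinact_filter_config`.
#' @examples
#' filter_config(snr_min = 3, min_files = 5)
#' @export
filter_config <- function(snr_min = 3, contribution_tol = 0.20,
                          min_transitions = 2L, min_files = 5L,
                          ratio_consistency_tol = 0.5) {
  stopifnot(
    snr_min > 0, contribution_tol > 0, ratio_consistency_tol > 0,
    min_transitions >= 1, min_files >= 1
  )
  structure(
    list(
      snr_min = snr_min,
      contribution_tol = contribution_tol,
      min_transitions = as.integer(min_transitions),
      min_files = as.integer(min_files),
      ratio_consistency_tol = ratio_consistency_tol
    ),
    class = "kinact_filter_config"
  )
}

#' @export
print.kinact_filter_config <- function(x, ...) {
  cat("<kinact filter config>\n")
  cat(sprintf("  S/N minimum              : %g x background\n", x$snr_min))
  cat(sprintf("  contribution tolerance   : %.2f (absolute fraction)\n",
              x$contribution_tol))
  cat(sprintf("  min transitions/peptide  : %d\n", x$min_transitions))
  cat(sprintf("  min files/peptide        : %d\n", x$min_files))
  cat(sprintf("  ratio consistency (log2) : %.2f\n", x$ratio_consistency_tol))
  invisible(x)
}
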