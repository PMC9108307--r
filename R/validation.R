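#' Admixture-estimation accuracy on simulated F1 hybrids
#'
#' Runs the leave-one-in estimator on a set of simulated F1 hybrids (true
#' admixture 0.5 by construction) and summarises accuracy as the mean squared
#' difference between the estimate and 0.5 and as the empirical central 95%
#' interval of the estimates (2.5 and 97.5 percentiles). Accuracy is computed
#' on raw (uncalibrated) estimates.
#'
#' @param hybrids a [genotype_matrix()] of F1 hybrids (see [hybridize()]).
#' @param wild_refs,farm_refs reference panels.
#' @param panel optional [select_panel()] result or locus-id vector.
#' @param cfg a [sampler_config()].
#' @param expected true admixture of the hybrids (0.5 for F1).
#' @return list of class `accuracy_report`: `n_markers`, `n_hybrids`, `mse`,
#'   `central_interval` (2.5/97.5 percentiles), `mean_estimate`, `estimates`
#'   (per-hybrid table).
#' @export
evaluate_hybrid_accuracy <- function(hybrids, wild_refs, farm_refs,
                                     panel = NULL, cfg = sampler_config(),
                                     expected = 0.5) {
  if (nrow(hybrids) < 20) {
    warning("fewer than 20 hybrids: the 95% interval will be unstable")
  }
  res <- leave_one_in(hybrids, wild_refs, farm_refs, cfg, panel)
  est <- res$admixture_raw[!res$failed]
  ci <- stats::quantile(est, c(0.025, 0.975), names = FALSE)
  n_markers <- if (is.null(panel)) ncol(hybrids) else {
    if (inherits(panel, "marker_panel")) panel$n_selected else length(panel)
  }
  structure(list(
    n_markers = n_markers,
    n_hybrids = nrow(hybrids),
    mse = mean((est - expected)^2),
    mean_estimate = mean(est),
    central_interval = ci,
    estimates = res
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("F1 accuracy: %d hybrids, %d markers\n", x$n_hybrids, x$n_markers))
  cat(sprintf("  mean estimate %.3f, MSE %.4f, central 95%% interval [%.3f, %.3f]\n",
              x$mean_estimate, x$mse, x$central_interval[1], x$central_interval[2]))
  invisible(x)
}

#' Calibrated admixture distribution summary for a population sample
#'
#' Calibrates raw p(wild) values with the reference constants, reports the
#' population mean calibrated admixture (one minus the calibrated mean wild
#' proportion) and the proportions of individuals falling into admixture bins.
#' Bins are half-open `[lower, upper)` except the last, which is closed.
#'
#' @param results a [leave_one_in()] result table (or any data frame with a
#'   `p_wild_raw` column).
#' @param constants a [compute_reference_constants()] result.
#' @param bin_edges increasing admixture bin edges; default deciles of
#'   \[0, 1\].
#' @return list of class `admixture_distribution`: `mean_calibrated_admixture`
#'   (the calibration applied to the population mean p(wild)), `bin_edges`,
#'   `bin_proportions`, and the per-individual calibrated values.
#' @export
admixture_distribution_summary <- function(results, constants,
                                           bin_edges = seq(0, 1, by = 0.1)) {
  p <- results$p_wild_raw
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no admixture results to summarise")
  cal_wild <- calibrate(p, constants)
  adm <- 1 - cal_wild
  mean_adm <- 1 - calibrate(mean(p), constants)
  # unclamped calibrated values can spill just outside the bin range; they are
  # counted in the boundary bins
  adm_b <- pmin(pmax(adm, min(bin_edges)), max(bin_edges))
  counts <- table(cut(adm_b, breaks = bin_edges, right = FALSE,
                      include.lowest = TRUE))
  structure(list(
    mean_calibrated_admixture = mean_adm,
    bin_edges = bin_edges,
    bin_proportions = as.numeric(counts) / sum(counts),
    bin_labels = names(counts),
    calibrated_admixture = adm
  ), class = "admixture_distribution")
}

#' @export
print.admixture_distribution <- function(x, ...) {
  cat(sprintf("mean calibrated admixture: %.1f%%\n",
              100 * x$mean_calibrated_admixture))
  for (i in seq_along(x$bin_proportions)) {
    cat(sprintf("  %-12s %5.1f%%\n", x$bin_labels[i], 100 * x$bin_proportions[i]))
  }
  invisible(x)
}
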