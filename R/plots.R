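# ggplot2 views of the main result types. These render the package's
# standard diagnostics: slope and CI histograms of a fitted panel,
# variance-vs-R2, and the sensitivity retention curve.

#' Histogram of modelable-protein slopes
#'
#' @param fits A `tier_fits` table or `factor_catalog`.
#' @param binwidth Histogram bin width in slope units.
#' @return A ggplot.
#' @export
plot_slope_distribution <- function(fits, binwidth = 0.05) {
  s <- extract_slopes(fits)
  ggplot2::ggplot(tibble::tibble(slope = s), ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue", colour = "white") +
    ggplot2::labs(
      x = "transformation factor (slope)", y = "proteins",
      title = "Slopes of modelable proteins"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of slope confidence half-widths
#'
#' @param fits A `tier_fits` table or `factor_catalog`.
#' @param gate Gate to mark (default 0.3); drawn as a dashed line.
#' @param binwidth Bin width.
#' @return A ggplot.
#' @export
plot_ci_histogram <- function(fits, gate = 0.3, binwidth = 0.025) {
  tbl <- tibble::as_tibble(fits)
  if ("tier" %in% names(tbl)) tbl <- dplyr::filter(tbl, !is.na(.data$tier))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$ci_halfwidth)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = gate, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "95% CI half-width of the slope", y = "proteins",
      title = "Slope confidence half-widths"
    ) +
    ggplot2::theme_minimal()
}

#' Variance vs model fit
#'
#' @param diagnostics Output of [variance_diagnostics()].
#' @param medium Which medium's variance to show ("serum" or "plasma").
#' @return A ggplot (log10 variance vs R-squared, coloured by modelability).
#' @export
plot_variance_diagnostics <- function(diagnostics, medium = c("serum", "plasma")) {
  medium <- match.arg(medium)
  col <- paste0(medium, "_variance")
  ggplot2::ggplot(
    diagnostics,
    ggplot2::aes(x = .data[[col]], y = .data$r2, colour = .data$modelable)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = paste(medium, "variance (NPX^2, log scale)"), y = "R-squared",
      title = "Within-cohort variance drives modelability"
    ) +
    ggplot2::theme_minimal()
}

#' Retention curve of a sensitivity sweep
#'
#' @param object A `sensitivity_sweep` table.
#' @param ... Unused.
#' @return A ggplot of retention and FP fraction against the applied factor.
#' @method autoplot sensitivity_sweep
#' @export
autoplot.sensitivity_sweep <- function(object, ...) {
  curve <- retention_curve(object)
  long <- tidyr::pivot_longer(
    dplyr::select(curve, "factor", "retention", "fp_fraction"),
    -"factor",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$factor, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::labs(
      x = "applied scaling factor", y = NULL,
      title = "Sensitivity of DEA findings to factor error"
    ) +
    ggplot2::theme_minimal()
}
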