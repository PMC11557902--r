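#' Plot an ORA result
#'
#' Fold enrichment against `-log10(FDR)` for every reported set, with the
#' significance threshold drawn as a dashed line.
#'
#' @param object An `ora_result` from [run_ora()].
#' @param alpha Significance threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ora_result
#' @export
autoplot.ora_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fold_enrichment, y = -log10(.data$fdr),
    colour = .data$fdr < alpha
  )) +
    ggplot2::geom_point(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "fold enrichment", y = expression(-log[10] ~ FDR))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot benchmark metrics against noise level
#'
#' Mean precision, recall and F1 per method across the noise grid, with
#' Monte-Carlo standard-error ribbons.
#'
#' @param study A `sim_study` from [run_simulation_study()].
#' @return A ggplot object, faceted by metric.
#' @export
plot_study_metrics <- function(study) {
  long <- study$summary |>
    tidyr::pivot_longer(
      cols = tidyr::matches("^(precision|recall|f1)_(mean|se)$"),
      names_to = c("metric", ".value"),
      names_pattern = "(.*)_(mean|se)"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$noise_sd, y = .data$mean, colour = .data$method,
    fill = .data$method
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se
    ), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "noise SD", y = "mean over replicates")
}

#' Plot Jaccard similarity against foreground size
#'
#' @param sweep A tibble from [run_foreground_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$size, y = .data$jaccard)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "foreground size (genes per direction)",
                  y = "Jaccard index of significant sets")
}

#' Plot down-sampling consistency
#'
#' Consistent-call counts (sensitivity) and inconsistent proportion
#' (realised false discovery rate) across subset sizes.
#'
#' @param consistency A tibble from [downsample_consistency()].
#' @return A ggplot object.
#' @export
plot_consistency <- function(consistency) {
  long <- consistency |>
    tidyr::pivot_longer(c("n_consistent", "prop_inconsistent"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$size), y = .data$value, fill = .data$method
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "subjects retained", y = NULL)
}
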