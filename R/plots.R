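#' Plot a reference-scheme sweep
#'
#' Coefficient of the anomaly term (with confidence band) against the sweep
#' parameter, annotated with the sample-average years-missed rate.
#'
#' @param object An `swb_sweep` from [reference_sweep()].
#' @param baseline Optional horizontal reference line (e.g. the lifetime-
#'   scheme estimate).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot swb_sweep
#' @export
autoplot.swb_sweep <- function(object, baseline = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$param, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
                         alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = if (object$scheme[1] == "preceding_years") "preceding years in reference"
          else "maximum age in reference",
      y = "anomaly coefficient (well-being per °C)",
      caption = sprintf("mean years-missed ranges %.2f-%.2f across the grid",
                        min(object$mean_years_missed),
                        max(object$mean_years_missed))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, linetype = "dashed")
  }
  p
}

#' Plot projected well-being impacts
#'
#' Ensemble-mean impacts per scenario under the updating and fixed reference
#' schemes; faint lines show individual climate models.
#'
#' @param object An `swb_projection` from [project_impacts()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot swb_projection
#' @export
autoplot.swb_projection <- function(object, ...) {
  ens <- ensemble_projection(object) |>
    tidyr::pivot_longer(c("impact_updating", "impact_fixed"),
                        names_to = "reference", values_to = "impact",
                        names_prefix = "impact_")
  models <- object |>
    dplyr::summarise(impact_updating = mean(.data$impact_updating),
                     .by = c("scenario", "model", "year"))
  ggplot2::ggplot(ens, ggplot2::aes(x = .data$year, y = .data$impact,
                                    linetype = .data$reference)) +
    ggplot2::geom_line(
      data = models,
      mapping = ggplot2::aes(x = .data$year, y = .data$impact_updating,
                             group = .data$model),
      inherit.aes = FALSE,
      alpha = 0.15
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = NULL, y = "projected well-being impact",
                  linetype = "reference") +
    ggplot2::theme_minimal()
}

#' Plot temperature-bin coefficients
#'
#' Day-count coefficients per 3 degC bin relative to the omitted comfort bin
#' (drawn at zero), with confidence intervals.
#'
#' @param fit An `swb_fit` estimated with `term = "bins"`.
#' @param conf.level Confidence level.
#' @return A ggplot.
#' @export
plot_bin_coefficients <- function(fit, conf.level = 0.95) {
  if (fit$term != "bins") abort("`fit` must use the bins term.")
  td <- tidy(fit, conf.level = conf.level)
  td <- td[td$term %in% fit$term_cols, ]
  spec <- fit$spec$bins
  td$bin <- factor(sub("^bin_", "", td$term),
                   levels = setdiff(spec$labels, spec$omitted_label))
  omitted <- tibble(bin = factor(spec$omitted_label,
                                 levels = c(levels(td$bin), spec$omitted_label)),
                    estimate = 0)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$bin, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_point(data = omitted, shape = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "temperature bin (°C)",
                  y = "effect per day vs omitted bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
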