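#' Plot group response proportions with optional model predictions
#'
#' Mean (+/- SEM) percentage of "yes" responses per asynchrony, coloured by
#' visual-noise level, optionally overlaid with one or more observers'
#' predicted psychometric curves.
#'
#' @param counts A counts tibble (canonical columns).
#' @param params Optional [observer_params()] whose predictions to overlay.
#' @param design Optional [rhi_design()] used to draw a smooth predicted
#'   curve; defaults to the range of asynchronies in `counts`.
#' @return A ggplot object.
#' @export
plot_detection_curves <- function(counts, params = NULL, design = NULL) {
  props <- descriptive_proportions(counts)
  props$noise <- factor(props$noise)
  p <- ggplot2::ggplot(props,
                       ggplot2::aes(x = .data$asynchrony_ms,
                                    y = .data$mean_pct_yes,
                                    colour = .data$noise)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_pct_yes - .data$sem_pct_yes,
                   ymax = .data$mean_pct_yes + .data$sem_pct_yes)
    ) +
    ggplot2::labs(x = "Asynchrony (ms)", y = "% \"yes\" responses",
                  colour = "Visual noise (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    s_grid <- seq(min(counts$asynchrony_ms), max(counts$asynchrony_ms),
                  length.out = 201)
    pred <- purrr::map_dfr(sort(unique(counts$noise)), function(nz) {
      tibble::tibble(
        asynchrony_ms = s_grid, noise = nz,
        pct = 100 * p_report_common(s_grid, params, nz)
      )
    })
    pred$noise <- factor(pred$noise)
    p <- p + ggplot2::geom_line(
      data = pred,
      ggplot2::aes(x = .data$asynchrony_ms, y = .data$pct,
                   colour = .data$noise),
      linewidth = 0.6, alpha = 0.8
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted observer against the data it was fitted to
#'
#' @param object An `"rhi_fit"` from [fit_observer()].
#' @param counts The counts table the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhi_fit <- function(object, counts, ...) {
  if (object$kind != "single") {
    stop("autoplot() supports single-task fits; plot extension fits per ",
         "task with plot_detection_curves()", call. = FALSE)
  }
  plot_detection_curves(counts, params = object$params) +
    ggplot2::ggtitle(paste0(object$model, " fit (logLik = ",
                            signif(object$logLik, 5), ")"))
}

#' Plot parameter recovery (true vs estimated)
#'
#' @param object A `"recovery_report"`.
#' @param ... Unused.
#' @return A ggplot object, one facet per parameter, identity line dashed.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$true, y = .data$estimated)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Generating value", y = "Recovered value") +
    ggplot2::theme_minimal()
}
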