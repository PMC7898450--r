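#' Plot methods for fitted objects
#'
#' `autoplot.lambda_scan` draws the BIC landscape over the regularization
#' grid as a heatmap with the selected cell marked; `autoplot.network_fit`
#' compares simulated and measured output activities per condition;
#' `autoplot.resample_summary` shows each parameter's resampling mean with a
#' +/- 1 SD ribbon.
#'
#' @param object The fitted object.
#' @param datasets For `autoplot.network_fit`: the list of
#'   [measurement_set()] objects the model was fit to.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lambda_scan
#' @export
autoplot.lambda_scan <- function(object, ...) {
  g <- tidy(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$log2_lu, y = .data$log2_lp,
                                  fill = .data$bic)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = g[g$best, ], colour = "white", shape = 4,
                        size = 3, stroke = 1.5) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "log2(lambda_uniformity)", y = "log2(lambda_pruning)",
                  fill = "BIC",
                  title = "Regularization landscape (selected cell marked)")
}

#' @rdname autoplot.lambda_scan
#' @method autoplot network_fit
#' @export
autoplot.network_fit <- function(object, datasets, ...) {
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  df <- purrr::map_dfr(datasets, function(d) {
    sim <- simulate_design(object$network, object$params, d$conditions,
                           d$context)
    long_sim <- tidyr::pivot_longer(sim, -"condition",
                                    names_to = "node", values_to = "simulated")
    long_meas <- tidyr::pivot_longer(d$values, -"condition",
                                     names_to = "node", values_to = "measured")
    out <- dplyr::inner_join(long_sim, long_meas, by = c("condition", "node"))
    out$context <- d$context
    out
  })
  long <- tidyr::pivot_longer(df, c("simulated", "measured"),
                              names_to = "kind", values_to = "activity")
  long$condition <- factor(long$condition, levels = unique(df$condition))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$activity,
                                     colour = .data$kind, group = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$node),
                        cols = ggplot2::vars(.data$context), scales = "free_x") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6)) +
    ggplot2::labs(x = NULL, y = "activity", colour = NULL,
                  title = "Model fit vs measurements")
}

#' @rdname autoplot.lambda_scan
#' @method autoplot resample_summary
#' @export
autoplot.resample_summary <- function(object, ...) {
  df <- tidy(object)
  df$param <- paste0(df$label, " [", df$context, "]")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$param)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = pmax(0, .data$mean - .data$sd),
                                          xmax = pmin(1, .data$mean + .data$sd))) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "parameter value (mean ± SD over resampling rounds)",
                  y = NULL)
}
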