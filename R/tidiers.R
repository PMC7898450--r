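#' Tidy a fitted logic model
#'
#' @param x A `network_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (label, context): `label`, `context`,
#'   `value`, `group`, and `shared` (whether the label is tied across all
#'   contexts in the fit's sharing structure).
#' @method tidy network_fit
#' @export
tidy.network_fit <- function(x, ...) {
  p <- as_tibble(x$params)
  n_ctx <- length(unique(p$context))
  by_lab <- table(p$label[!duplicated(paste(p$label, p$group))])
  p$shared <- unname(by_lab[p$label] == 1) & n_ctx > 1
  p
}

#' @rdname tidy.network_fit
#' @method glance network_fit
#' @export
glance.network_fit <- function(x, ...) {
  tibble(
    mse = x$mse,
    penalty_pruning = x$penalty_pruning,
    penalty_uniformity = x$penalty_uniformity,
    total_loss = x$total_loss,
    k = x$n_distinct_params,
    n_obs = x$n_obs,
    bic = bic(x$mse, x$n_obs, x$n_distinct_params),
    converged = x$converged,
    best_start = x$best_start,
    n_iter = length(x$trace) - 1L
  )
}

#' @rdname tidy.network_fit
#' @method tidy lambda_scan
#' @export
tidy.lambda_scan <- function(x, ...) {
  g <- as_tibble(x$grid)
  g$best <- seq_len(nrow(g)) == x$best
  g
}

#' @rdname tidy.network_fit
#' @method glance lambda_scan
#' @export
glance.lambda_scan <- function(x, ...) {
  b <- x$grid[x$best, ]
  tibble(log2_lambda_pruning = b$log2_lp,
         log2_lambda_uniformity = b$log2_lu,
         bic = b$bic, mse = b$mse, k = b$k,
         n_cells = nrow(x$grid))
}

#' @rdname tidy.network_fit
#' @method tidy reduced_model
#' @export
tidy.reduced_model <- function(x, ...) {
  p <- tidy(x$fit)
  p$merged <- p$label %in% x$merged_labels
  p
}

#' @rdname tidy.network_fit
#' @method glance reduced_model
#' @export
glance.reduced_model <- function(x, ...) {
  g <- glance(x$fit)
  g$n_edges_removed <- nrow(x$removed_edges)
  g$n_merged_labels <- length(x$merged_labels)
  g$n_context_specific_labels <- length(x$context_specific_labels)
  g
}

#' @rdname tidy.network_fit
#' @method tidy resample_summary
#' @export
tidy.resample_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "resample_summary")
  for (a in c("n_resamples", "seeds", "n_dropped", "noise_scale")) {
    attr(out, a) <- NULL
  }
  out
}

#' Parameter table in the layout of a published model-comparison table
#'
#' Combines fits of the same network under different sharing assumptions
#' into one wide table: a row per parameter label, a value column per model,
#' and (when a [resample_parameters()] summary is supplied) an `sd` column
#' for the final model.
#'
#' @param fits Named list of `network_fit` objects (e.g. `single`, `final`).
#' @param resample Optional `resample_summary` for the final model.
#' @return Wide tibble: `label`, then `<model>.<context>` (or `<model>` when
#'   the model's values are uniform across contexts) value columns.
#' @export
parameter_table <- function(fits, resample = NULL) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  blocks <- purrr::imap(fits, function(ft, nm) {
    p <- tidy(ft)
    if (all(p$shared)) {
      out <- dplyr::distinct(p[, c("label", "value")])
      names(out)[2] <- nm
      out
    } else {
      tidyr::pivot_wider(p[, c("label", "context", "value")],
                         names_from = "context", values_from = "value",
                         names_prefix = paste0(nm, "."))
    }
  })
  out <- purrr::reduce(blocks, dplyr::full_join, by = "label")
  if (!is.null(resample)) {
    rs <- tidy(resample)
    sds <- dplyr::summarise(rs, sd = max(.data$sd), .by = "label")
    names(sds)[2] <- "final_sd"
    out <- dplyr::left_join(out, sds, by = "label")
  }
  out
}
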