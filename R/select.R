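#' Bayesian Information Criterion for a fitted logic model
#'
#' Gaussian-error BIC up to additive constants:
#' \eqn{\mathrm{BIC} = N \ln(\mathrm{MSE}) + k \ln(N)}, with \eqn{N} the
#' number of (non-missing) measurements and \eqn{k} the effective number of
#' distinct parameters (see [count_distinct_parameters()]).
#'
#' @param mse Positive mean squared error of the fit.
#' @param n_measurements Number of measurements \eqn{N}.
#' @param k_distinct Effective parameter count \eqn{k}.
#' @return Scalar BIC; an exact zero MSE returns `-Inf` with a warning.
#' @export
bic <- function(mse, n_measurements, k_distinct) {
  stopifnot(n_measurements >= 0, k_distinct >= 0, mse >= 0)
  if (mse == 0) {
    warn("MSE is exactly 0; BIC returned as -Inf")
    return(-Inf)
  }
  n_measurements * log(mse) + k_distinct * log(n_measurements)
}

#' Scan the regularization grid and select the minimal-BIC model
#'
#' Fits the network once per cell of a (log2 lambda_pruning, log2
#' lambda_uniformity) grid and scores every convergent cell by [bic()]. The
#' winning cell minimizes the BIC; ties are broken toward larger lambdas
#' (the sparser model).
#'
#' Because the penalties bias the fitted weights, each cell's BIC is
#' computed on a debiased refit: the parameter-sharing structure the
#' regularized fit selects (labels with cross-context SD below `merge_tol`
#' tied) is frozen and the model refit without penalties, so cells compete
#' on model *structure* rather than on shrinkage bias — the same logic as
#' relaxed sparse regression.
#'
#' @param network A [logic_network()].
#' @param datasets List of [measurement_set()] objects.
#' @param log2_lambda_pruning,log2_lambda_uniformity Numeric vectors of
#'   log2 lambda values spanning the grid (use `-Inf` for an unpenalized
#'   axis). Defaults cover `seq(-14, 0, by = 2)` on both axes.
#' @param config A [fit_config()]; each cell reuses its seed, so the scan is
#'   deterministic.
#' @param merge_tol SD threshold handed to [count_distinct_parameters()]
#'   when computing each cell's effective parameter count.
#' @return Object of class `lambda_scan`: a list with `grid` (tibble of
#'   cells: `log2_lp`, `log2_lu`, `mse_regularized`, `mse`, `k`, `bic`,
#'   `converged`), `fits` (list of debiased `network_fit`, one per cell),
#'   `regularized_fits` (the penalized fits), `best` (row index of the
#'   winning cell) and `best_fit`.
#' @export
scan_lambda_grid <- function(network, datasets,
                             log2_lambda_pruning = seq(-14, 0, by = 2),
                             log2_lambda_uniformity = seq(-14, 0, by = 2),
                             config = fit_config(),
                             merge_tol = 0.01) {
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  cells <- tidyr::expand_grid(log2_lp = log2_lambda_pruning,
                              log2_lu = log2_lambda_uniformity)
  contexts <- vapply(datasets, function(d) d$context, character(1))
  fl <- free_labels(network)
  fits <- vector("list", nrow(cells))
  reg_fits <- vector("list", nrow(cells))
  res <- vector("list", nrow(cells))
  refit_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$lambda_pruning <- 2^cells$log2_lp[i]
    cfg$lambda_uniformity <- 2^cells$log2_lu[i]
    ft <- fit_network(network, datasets, cfg)
    # freeze the sharing structure this cell selects and refit unpenalized
    # (cells inducing the same structure share one cached refit)
    sds <- label_context_sd(ft$params)
    sharing <- tidyr::expand_grid(label = fl$label, context = contexts)
    tied <- sharing$label %in% names(sds)[sds < merge_tol]
    sharing$group <- ifelse(tied, sharing$label,
                            paste0(sharing$label, "@", sharing$context))
    key <- paste(sharing$group, collapse = "|")
    refit <- refit_cache[[key]]
    if (is.null(refit)) {
      refit <- fit_network(network, datasets, config, sharing = sharing)
      refit_cache[[key]] <- refit
    }
    k <- count_distinct_parameters(refit$params, merge_tol)
    fits[[i]] <- refit
    reg_fits[[i]] <- ft
    res[[i]] <- tibble(
      mse_regularized = ft$mse,
      mse = refit$mse, k = k,
      bic = bic(refit$mse, refit$n_obs, k),
      converged = ft$converged && refit$converged
    )
  }
  grid <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  usable <- which(grid$converged)
  if (length(usable) == 0) {
    warn("no grid cell converged; selecting among all cells")
    usable <- seq_len(nrow(grid))
  } else if (length(usable) < nrow(grid)) {
    warn(paste0(nrow(grid) - length(usable),
                " non-convergent grid cell(s) excluded from selection"))
  }
  # arg-min BIC; ties toward larger lambdas (sparser model)
  ord <- usable[order(grid$bic[usable],
                      -grid$log2_lu[usable],
                      -grid$log2_lp[usable])]
  best <- ord[1]
  structure(
    list(grid = grid, fits = fits, regularized_fits = reg_fits,
         best = best, best_fit = fits[[best]], merge_tol = merge_tol),
    class = "lambda_scan"
  )
}

#' @export
print.lambda_scan <- function(x, ...) {
  b <- x$grid[x$best, ]
  cat("<lambda_scan> ", nrow(x$grid), " cells; best at log2(lambda_pruning) = ",
      b$log2_lp, ", log2(lambda_uniformity) = ", b$log2_lu,
      " (BIC ", signif(b$bic, 6), ", MSE ", signif(b$mse, 4),
      ", k = ", b$k, ")\n", sep = "")
  invisible(x)
}

#' Edge flux of a fitted model
#'
#' The flux of an edge is its fitted weight multiplied by the mean
#' steady-state activity of its source node, averaged over every condition
#' of every context. Low-flux edges carry no signal anywhere in the design
#' and are removed when fixing the final topology.
#'
#' @param network A [logic_network()].
#' @param params A [param_set()].
#' @param datasets List of [measurement_set()] objects supplying the
#'   conditions (per context).
#' @return Tibble with columns `from`, `to`, `sign`, `label`, `flux`.
#' @export
edge_flux <- function(network, params, datasets) {
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  cn <- compile_network(network)
  e <- network$edges
  acc <- numeric(nrow(e))
  n_cond <- 0
  for (d in datasets) {
    w <- edge_weights(network, params, d$context)
    fw <- forward_pass(cn, w, condition_matrix(network, d$conditions))
    src_act <- fw$A[, cn$from_i, drop = FALSE]
    acc <- acc + colSums(src_act) * w
    n_cond <- n_cond + nrow(d$conditions)
  }
  tibble(from = e$from, to = e$to, sign = e$sign, label = e$label,
         flux = unname(acc) / n_cond)
}

#' Reduce the topology of the selected model and refit unregularized
#'
#' Implements the final-model procedure: edges whose [edge_flux()] falls
#' below `flux_tol` are removed; parameter labels whose values agree across
#' contexts (SD below `sd_tol`) are hard-tied into one shared parameter; the
#' reduced model is then refit on the full data with both lambdas at zero,
#' giving unbiased final estimates.
#'
#' @param network A [logic_network()].
#' @param datasets List of [measurement_set()] objects.
#' @param best_fit The selected `network_fit` (e.g. `scan$best_fit`).
#' @param flux_tol Flux threshold below which an edge is removed.
#' @param sd_tol Cross-context SD threshold below which a label is merged.
#' @param config A [fit_config()] for the refit.
#' @return Object of class `reduced_model`: list with `network` (pruned),
#'   `fit` (the unregularized refit), `removed_edges` (tibble),
#'   `merged_labels` (character), `context_specific_labels` (character) and
#'   `sharing` (the tying table used).
#' @export
reduce_and_refit <- function(network, datasets, best_fit,
                             flux_tol = 0.01, sd_tol = 0.01,
                             config = fit_config()) {
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  flux <- edge_flux(network, best_fit$params, datasets)
  drop <- flux$flux < flux_tol
  removed <- flux[drop, ]
  kept <- network$edges[!drop, ]
  if (nrow(kept) == 0) abort("reduction removed every edge")
  roles <- network$nodes[network$nodes$node %in% unique(c(kept$from, kept$to)), ]
  reduced <- tryCatch(
    logic_network(kept, roles = roles),
    error = function(e) {
      abort(paste0("reduction disconnected the network: ",
                   conditionMessage(e)))
    }
  )
  contexts <- vapply(datasets, function(d) d$context, character(1))
  fl <- free_labels(reduced)
  prev <- best_fit$params[best_fit$params$label %in% fl$label, ]
  sds <- label_context_sd(prev)
  # labels free in the reduced net but absent from the previous fit (an edge
  # lost its sibling) start shared
  sds <- sds[names(sds) %in% fl$label]
  merged <- union(names(sds)[sds < sd_tol], setdiff(fl$label, names(sds)))
  specific <- setdiff(fl$label, merged)
  sharing <- tidyr::expand_grid(label = fl$label, context = contexts)
  sharing$group <- ifelse(sharing$label %in% merged, sharing$label,
                          paste0(sharing$label, "@", sharing$context))
  fit <- fit_network(reduced, datasets, config, sharing = sharing)
  structure(
    list(network = reduced, fit = fit, removed_edges = removed,
         merged_labels = merged, context_specific_labels = specific,
         sharing = sharing, flux = flux,
         flux_tol = flux_tol, sd_tol = sd_tol),
    class = "reduced_model"
  )
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("<reduced_model> ", nrow(x$network$edges), " edges (",
      nrow(x$removed_edges), " removed by flux < ", x$flux_tol, "), ",
      length(x$merged_labels), " shared + ",
      length(x$context_specific_labels), " context-specific labels\n",
      "  final refit MSE ", signif(x$fit$mse, 4), "\n", sep = "")
  invisible(x)
}

#' Fit the all-tied "single model"
#'
#' Convenience wrapper tying every free parameter across all contexts, the
#' fully shared counterpart of the context-specific models.
#'
#' @inheritParams fit_network
#' @return A `network_fit`.
#' @export
fit_single_model <- function(network, datasets, config = fit_config()) {
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  contexts <- vapply(datasets, function(d) d$context, character(1))
  fl <- free_labels(network)
  sharing <- tidyr::expand_grid(label = fl$label, context = contexts)
  sharing$group <- sharing$label
  fit_network(network, datasets, config, sharing = sharing)
}
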