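#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis. `read_run_config()`
#' loads the same structure from a flat YAML key/value file (paths are
#' resolved relative to the file).
#'
#' @param network Path to a network file, or a [logic_network()].
#' @param data Named list: context name -> measurement file path or
#'   [measurement_set()].
#' @param log2_lambda_pruning,log2_lambda_uniformity Grid axes for
#'   [scan_lambda_grid()].
#' @param n_starts,seed,tol,max_iter Passed to [fit_config()].
#' @param flux_tol,sd_tol Reduction tolerances for [reduce_and_refit()].
#' @param n_resamples,noise_scale Resampling settings for
#'   [resample_parameters()].
#' @param out_dir Output directory (created if needed); `NULL` writes no
#'   files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(network, data,
                       log2_lambda_pruning = seq(-14, 0, by = 2),
                       log2_lambda_uniformity = seq(-14, 0, by = 2),
                       n_starts = 20, seed = 1, tol = 1e-9, max_iter = 5000,
                       flux_tol = 0.01, sd_tol = 0.01,
                       n_resamples = 20, noise_scale = 1,
                       out_dir = NULL) {
  structure(
    list(network = network, data = data,
         log2_lambda_pruning = log2_lambda_pruning,
         log2_lambda_uniformity = log2_lambda_uniformity,
         n_starts = n_starts, seed = seed, tol = tol, max_iter = max_iter,
         flux_tol = flux_tol, sd_tol = sd_tol,
         n_resamples = n_resamples, noise_scale = noise_scale,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param file Path to a YAML config file with the same keys; `data` is a
#'   mapping context -> file path.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p))) {
      file.path(base, p)
    } else p
  }
  y$network <- resolve(y$network)
  y$data <- lapply(y$data, resolve)
  do.call(run_config, y)
}

#' Run the full contextualization pipeline
#'
#' Executes, in order: regularization-grid scan with BIC selection
#' ([scan_lambda_grid()]), topology reduction and unregularized refit
#' ([reduce_and_refit()]), the all-tied single model ([fit_single_model()]),
#' and parameter-uncertainty resampling ([resample_parameters()]). When
#' `config$out_dir` is set, writes `bic_grid.tsv`, `parameter_table.tsv`,
#' `fit_vs_measurement.tsv`, `final_network.tsv` and `summary.txt`; every
#' file header records the seed and a hash of the configuration. A stage
#' failure aborts with the stage name; earlier outputs are preserved.
#'
#' @param config A [run_config()].
#' @return Invisible list of class `pipeline_result` with elements `scan`,
#'   `reduced`, `single`, `resample`, `parameter_table`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  network <- if (inherits(config$network, "logic_network")) config$network
             else read_network(config$network)
  datasets <- purrr::imap(config$data, function(d, ctx) {
    if (inherits(d, "measurement_set")) d
    else read_measurements(d, network, ctx)
  })
  datasets <- unname(datasets)
  fcfg <- fit_config(n_starts = config$n_starts, seed = config$seed,
                     tol = config$tol, max_iter = config$max_iter)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cfg_hash <- config_hash(config)
  stamp <- paste0("# seed: ", config$seed, "\n# config_hash: ", cfg_hash)
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writeLines(stamp, path)
    suppressWarnings(
      readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                       progress = FALSE)
    )
    invisible(path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  scan <- stage("scan", scan_lambda_grid(
    network, datasets,
    log2_lambda_pruning = config$log2_lambda_pruning,
    log2_lambda_uniformity = config$log2_lambda_uniformity,
    config = fcfg, merge_tol = config$sd_tol
  ))
  emit(tidy(scan), "bic_grid.tsv")

  reduced <- stage("reduce", reduce_and_refit(
    network, datasets, scan$best_fit,
    flux_tol = config$flux_tol, sd_tol = config$sd_tol, config = fcfg
  ))
  single <- stage("single_model", fit_single_model(network, datasets, fcfg))

  resample <- stage("resample", resample_parameters(
    reduced$network, datasets, sharing = reduced$sharing,
    n = config$n_resamples, noise_scale = config$noise_scale,
    base_seed = config$seed, config = fcfg
  ))

  ptab <- parameter_table(list(single = single, final = reduced$fit),
                          resample = resample)
  emit(ptab, "parameter_table.tsv")

  fitcmp <- purrr::map_dfr(datasets, function(d) {
    sim <- simulate_design(reduced$network, reduced$fit$params,
                           d$conditions, d$context)
    long_sim <- tidyr::pivot_longer(sim, -"condition", names_to = "node",
                                    values_to = "simulated")
    long_meas <- tidyr::pivot_longer(d$values, -"condition", names_to = "node",
                                     values_to = "measured")
    out <- dplyr::inner_join(long_sim, long_meas, by = c("condition", "node"))
    out$context <- d$context
    out
  })
  emit(fitcmp, "fit_vs_measurement.tsv")

  if (!is.null(out_dir)) {
    write_network(reduced$network, file.path(out_dir, "final_network.tsv"))
    best <- glance(scan)
    summary_lines <- c(
      stamp,
      paste0("contexts: ", paste(vapply(datasets, `[[`, character(1),
                                        "context"), collapse = ", ")),
      paste0("n_obs: ", reduced$fit$n_obs),
      paste0("best log2(lambda_pruning): ", best$log2_lambda_pruning),
      paste0("best log2(lambda_uniformity): ", best$log2_lambda_uniformity),
      paste0("single-model MSE: ", format(single$mse)),
      paste0("final-model MSE: ", format(reduced$fit$mse)),
      paste0("edges removed: ", nrow(reduced$removed_edges)),
      paste0("shared labels: ", length(reduced$merged_labels)),
      paste0("context-specific labels: ",
             length(reduced$context_specific_labels))
    )
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }

  invisible(structure(
    list(scan = scan, reduced = reduced, single = single,
         resample = resample, parameter_table = ptab, config = config),
    class = "pipeline_result"
  ))
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  keep$network <- if (inherits(keep$network, "logic_network")) {
    keep$network$edges
  } else keep$network
  keep$data <- lapply(keep$data, function(d) {
    if (inherits(d, "measurement_set")) list(d$context, d$values) else d
  })
  rlang::hash(keep)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$scan)
  print(x$reduced)
  cat("  single-model MSE ", signif(x$single$mse, 4), "\n", sep = "")
  invisible(x)
}
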