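#' Perturb a measurement set with Gaussian noise
#'
#' Adds independent Gaussian noise to each measured activity, with standard
#' deviation proportional to the measurement's SEM (when present) or to a
#' global scale, and clips the result back onto \[0, 1\]:
#' `value* = clip(value + N(0, noise_scale * sem), 0, 1)`.
#'
#' @param dataset A [measurement_set()].
#' @param noise_scale Nonnegative proportionality constant; with SEMs
#'   present the per-cell SD is `noise_scale * sem`, otherwise `noise_scale`
#'   itself is the SD of every cell.
#' @param seed Integer seed; the perturbation is reproducible.
#' @return A new [measurement_set()] with perturbed values (SEMs unchanged).
#' @export
perturb_measurements <- function(dataset, noise_scale, seed) {
  stopifnot(inherits(dataset, "measurement_set"))
  if (noise_scale < 0) abort("`noise_scale` must be nonnegative")
  out_cols <- setdiff(names(dataset$values), "condition")
  vals <- as.matrix(dataset$values[, out_cols, drop = FALSE])
  if (!is.null(dataset$sem)) {
    sdm <- as.matrix(dataset$sem[, out_cols, drop = FALSE]) * noise_scale
    sdm[is.na(sdm)] <- noise_scale
  } else {
    sdm <- matrix(noise_scale, nrow(vals), ncol(vals))
  }
  set.seed(seed)
  eps <- matrix(rnorm(length(vals), sd = 1), nrow(vals), ncol(vals)) * sdm
  pert <- pmin(pmax(vals + eps, 0), 1)
  pert[is.na(vals)] <- NA_real_
  new_vals <- dataset$values
  new_vals[out_cols] <- as.data.frame(pert)
  measurement_set(dataset$context, dataset$conditions, new_vals,
                  sem = dataset$sem)
}

#' Parameter uncertainty by noise resampling
#'
#' Refits the final model on `n` noise-perturbed copies of the measurements
#' and summarizes each parameter by the mean and standard deviation of its
#' refitted values — the resampling SDs quoted alongside final parameter
#' estimates.
#'
#' @param network The (reduced) [logic_network()] to refit.
#' @param datasets List of [measurement_set()] objects.
#' @param sharing Sharing table of the final topology (see [fit_network()]),
#'   typically `reduced$sharing`; `NULL` for untied parameters.
#' @param n Number of resampling rounds.
#' @param noise_scale Passed to [perturb_measurements()].
#' @param base_seed Integer; round `i` perturbs with seed `base_seed + i`.
#' @param config A [fit_config()] for the refits (lambdas are forced to 0).
#' @return Object of class `resample_summary`: tibble with columns `label`,
#'   `context`, `group`, `mean`, `sd`, plus attributes `n_resamples`,
#'   `seeds`, `n_dropped`.
#' @export
resample_parameters <- function(network, datasets, sharing = NULL, n = 20,
                                noise_scale = 1, base_seed = 1,
                                config = fit_config()) {
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  stopifnot(n >= 1)
  config$lambda_pruning <- 0
  config$lambda_uniformity <- 0
  seeds <- base_seed + seq_len(n)
  draws <- list()
  dropped <- 0
  for (i in seq_len(n)) {
    pert <- lapply(seq_along(datasets), function(j) {
      perturb_measurements(datasets[[j]], noise_scale,
                           seed = seeds[i] * 131 + j)
    })
    ft <- fit_network(network, pert, config, sharing = sharing)
    if (!ft$converged) {
      dropped <- dropped + 1
      next
    }
    p <- ft$params
    p$round <- i
    draws[[length(draws) + 1]] <- p
  }
  if (length(draws) == 0) abort("every resampling round failed to converge")
  if (dropped > 0) {
    warn(paste0(dropped, " non-convergent resampling round(s) dropped"))
  }
  all <- dplyr::bind_rows(draws)
  out <- dplyr::summarise(
    all,
    mean = mean(.data$value),
    sd = if (dplyr::n() < 2) 0 else sd(.data$value),
    .by = c("label", "context")
  )
  out <- out[order(match(out$label, unique(all$label))), ]
  structure(
    out,
    n_resamples = length(draws),
    seeds = seeds,
    n_dropped = dropped,
    noise_scale = noise_scale,
    class = c("resample_summary", class(out))
  )
}

#' @export
print.resample_summary <- function(x, ...) {
  cat("<resample_summary> ", attr(x, "n_resamples"), " rounds (",
      attr(x, "n_dropped"), " dropped), noise scale ",
      attr(x, "noise_scale"), "\n", sep = "")
  NextMethod()
}
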