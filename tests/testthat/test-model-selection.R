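test_that("BIC follows N log(MSE) + k log(N)", {
  expect_equal(bic(1, 100, 0), 0)
  expect_equal(bic(0.05, 80, 7) - bic(0.05, 80, 6), log(80))
  expect_equal(bic(0.02, 288, 69), 288 * log(0.02) + 69 * log(288))
  expect_warning(val <- bic(0, 100, 3), "-Inf")
  expect_identical(val, -Inf)
})

test_that("distinct-parameter counting treats context-specific labels per context", {
  uniform <- param_set(tibble::tibble(
    label = rep(paste0("k", 1:10), each = 4),
    context = rep(letters[1:4], 10),
    value = rep(stats::runif(10), each = 4),
    group = rep(paste0("k", 1:10), each = 4)
  ))
  expect_equal(count_distinct_parameters(uniform), 10)

  # the published sharing arithmetic: 63 of 69 labels uniform over 4 cell
  # lines gives 63 + 6 * 4 = 87 effective parameters
  vals <- matrix(rep(stats::runif(69, 0.1, 0.7), each = 4), nrow = 4)
  vals[4, 1:6] <- vals[4, 1:6] + 0.15
  prm <- param_set(tibble::tibble(
    label = rep(paste0("p", 1:69), each = 4),
    context = rep(letters[1:4], 69),
    value = as.vector(vals)
  ))
  expect_equal(count_distinct_parameters(prm, merge_tol = 0.01), 63 + 6 * 4)

  # brute-force SD thresholding oracle on random perturbations
  withr::with_seed(13, {
    for (i in 1:5) {
      base <- stats::runif(8, 0.2, 0.6)
      m <- matrix(rep(base, 3), nrow = 8)
      hit <- sample(8, 3)
      m[hit, 2] <- m[hit, 2] + stats::runif(3, 0.05, 0.3)
      prm2 <- param_set(tibble::tibble(
        label = rep(paste0("q", 1:8), 3),
        context = rep(c("a", "b", "c"), each = 8),
        value = as.vector(m)
      ))
      tol <- 0.01
      brute <- sum(apply(m, 1, stats::sd) < tol) +
        3 * sum(apply(m, 1, stats::sd) >= tol)
      expect_equal(count_distinct_parameters(prm2, tol), brute)
    }
  })
})

test_that("edge flux is weight times mean source activity", {
  net <- logic_network(
    data.frame(from = c("A", "B"), to = "C", sign = "->"),
    outputs = "C"
  )
  prm <- param_set(tibble::tibble(label = c("A_C", "B_C"), context = "x",
                                  value = c(0, 1)), network = net)
  conds <- tibble::tibble(condition = c("c1", "c2"), A = c(1, 0), B = c(1, 0))
  ms <- measurement_set("x", conds,
                        tibble::tibble(condition = c("c1", "c2"),
                                       C = c(0.5, 0)),
                        network = net)
  fx <- edge_flux(net, prm, list(ms))
  expect_equal(fx$flux[fx$label == "A_C"], 0)            # weight 0
  expect_equal(fx$flux[fx$label == "B_C"], 1 * 0.5)      # weight * mean act

  # brute-force recomputation condition by condition on a random fixture
  case <- random_dag_case(77)
  ms2 <- measurement_set("ctx", case$conditions, {
    sim <- simulate_design(case$network, case$params, case$conditions, "ctx")
    sim
  }, network = case$network)
  fx2 <- edge_flux(case$network, case$params, list(ms2))
  for (i in seq_len(nrow(fx2))) {
    acts <- vapply(seq_len(nrow(case$conditions)), function(j) {
      st <- steady_state(case$network, case$params, case$conditions[j, ], "ctx")
      st$activity[st$node == fx2$from[i]]
    }, numeric(1))
    e <- case$network$edges
    n_act <- table(e$to[e$sign == "activating"])
    w <- if (fx2$sign[i] == "activating" && n_act[[fx2$to[i]]] == 1) 1 else
      case$params$value[case$params$label == fx2$label[i] &
                          case$params$context == "ctx"]
    expect_equal(fx2$flux[i], w * mean(acts))
  }
})

test_that("a degenerate lambda grid returns the unregularized fit", {
  case <- chain_case(seed = 4, noise = 0.02)
  cfg <- quick_config(seed = 4)
  sc <- scan_lambda_grid(case$network, case$datasets,
                         log2_lambda_pruning = -Inf,
                         log2_lambda_uniformity = -Inf, config = cfg)
  expect_equal(nrow(sc$grid), 1)
  plain <- fit_network(case$network, case$datasets, cfg)
  expect_identical(sc$regularized_fits[[1]]$params, plain$params)
  expect_equal(sc$grid$mse_regularized[1], plain$mse)
  # the debiasing refit can only tie parameters, never worsen structure
  expect_lte(sc$best_fit$n_distinct_params, plain$n_distinct_params)
})

test_that("grid selection is invariant to enumeration order and prefers sparser ties", {
  case <- chain_case(seed = 8, n_diffs = 1, noise = 0.03)
  cfg <- quick_config(seed = 8)
  lus <- c(-10, -6, -2)
  sc1 <- scan_lambda_grid(case$network, case$datasets, -8, lus, config = cfg)
  sc2 <- scan_lambda_grid(case$network, case$datasets, -8, rev(lus),
                          config = cfg)
  expect_equal(glance(sc1)$log2_lambda_uniformity,
               glance(sc2)$log2_lambda_uniformity)
  expect_equal(glance(sc1)$bic, glance(sc2)$bic)
  # an explicit tie is broken toward the larger lambda
  g <- sc1$grid
  g$bic <- 1
  fake <- structure(list(grid = g, fits = sc1$fits,
                         best = order(-g$log2_lu, -g$log2_lp)[1],
                         merge_tol = 0.01),
                    class = "lambda_scan")
  expect_equal(fake$grid$log2_lu[fake$best], max(lus))
})

test_that("reduction removes silenced edges, merges uniform labels and refits", {
  # truth with one zero-weight edge: the I2 drug has no effect on C
  net <- chain_network()
  prm <- param_set(tibble::tibble(
    label = rep(c("S1_M", "S2_M", "I1_B", "M_C", "S2_C", "I2_C"), 2),
    context = rep(c("X", "Y"), each = 6),
    value = rep(c(0.35, 0.65, 0.8, 0.6, 0.4, 0), 2),
    group = rep(c("S1_M", "S2_M", "I1_B", "M_C", "S2_C", "I2_C"), 2)
  ), network = net)
  truth <- structure(
    list(network = net, params = prm,
         context_diffs = tibble::tibble(label = character(),
                                        context = character()),
         noise_scale = 0, seed = 1),
    class = "ground_truth"
  )
  datasets <- lapply(c("X", "Y"), function(cx) {
    simulate_dataset(truth, chain_design(), cx)
  })
  cfg <- quick_config(seed = 12, n_starts = 3)
  ft <- fit_network(net, datasets, cfg)
  red <- reduce_and_refit(net, datasets, ft, config = cfg)
  expect_true("I2_C" %in% red$removed_edges$label)
  expect_true(all(red$removed_edges$flux < red$flux_tol))
  # all surviving labels were uniform in truth: everything merges
  expect_length(red$context_specific_labels, 0)
  expect_s3_class(red$network, "logic_network")
  expect_false("I2" %in% red$network$edges$from)

  # the reduced refit cannot beat nor be beaten structurally: its MSE is no
  # worse than the fully tied single model on the same data
  single <- fit_single_model(net, datasets, cfg)
  expect_lte(red$fit$mse, single$mse + 1e-8)
  expect_lte(red$fit$n_distinct_params, ft$n_distinct_params)
})

test_that("reduction refuses to disconnect an output", {
  net <- logic_network(
    data.frame(from = c("A", "B"), to = c("B", "C"), sign = "->"),
    outputs = "C"
  )
  ms <- measurement_set(
    "x",
    tibble::tibble(condition = c("c1", "c2"), A = c(0, 0)),
    tibble::tibble(condition = c("c1", "c2"), C = c(0, 0)),
    network = net
  )
  cfg <- quick_config(seed = 1, n_starts = 1, max_iter = 10)
  ft <- fit_network(net, list(ms), cfg)
  # A is always off, so every edge has zero flux
  expect_error(reduce_and_refit(net, list(ms), ft, config = cfg),
               "removed every edge|disconnected")
})
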