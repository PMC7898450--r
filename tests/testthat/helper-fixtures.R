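# Independent oracle for the steady-state semantics: damped synchronous
# fixed-point iteration from random initial states, written directly against
# the edge list (no topological order, no code shared with forward_pass).
oracle_steady_state <- function(network, params, condition, context,
                                n_starts = 50, tol = 1e-9, alpha = 0.5) {
  nodes <- network$nodes$node
  e <- network$edges
  n_act <- table(e$to[e$sign == "activating"])
  w <- vapply(seq_len(nrow(e)), function(i) {
    if (e$sign[i] == "activating" && n_act[[e$to[i]]] == 1) {
      1
    } else {
      params$value[params$label == e$label[i] & params$context == context]
    }
  }, numeric(1))
  ins <- input_nodes(network)
  free <- setdiff(nodes, ins)
  ae_of <- lapply(free, function(v) which(e$to == v & e$sign == "activating"))
  ie_of <- lapply(free, function(v) which(e$to == v & e$sign == "inhibiting"))
  names(ae_of) <- names(ie_of) <- free
  one_run <- function() {
    x <- stats::setNames(stats::runif(length(nodes)), nodes)
    for (nm in ins) x[nm] <- condition[[nm]]
    for (iter in 1:5000) {
      xn <- x
      for (v in free) {
        ae <- ae_of[[v]]
        ie <- ie_of[[v]]
        s <- if (length(ae)) sum(w[ae] * x[e$from[ae]]) else 0
        p <- 1
        for (k in ie) p <- p * (1 - w[k] * x[e$from[k]])
        xn[v] <- s * p
      }
      xn <- (1 - alpha) * x + alpha * xn
      delta <- max(abs(xn - x))
      x <- xn
      if (delta < tol) break
    }
    x
  }
  t(replicate(n_starts, one_run()))
}

# Random small DAG with roles, random valid parameters and conditions.
random_dag_case <- function(seed, max_nodes = 8, contexts = "ctx") {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  nodes <- paste0("n", seq_len(n))
  n_in <- sample(1:2, 1)
  edges <- list()
  for (j in (n_in + 1):n) {
    parents <- sample(seq_len(j - 1), size = sample(1:min(3, j - 1), 1))
    for (p in parents) {
      edges[[length(edges) + 1]] <- data.frame(
        from = nodes[p], to = nodes[j],
        sign = if (stats::runif(1) < 0.75) "->" else "-|"
      )
    }
  }
  edges <- dplyr::bind_rows(edges)
  edges <- edges[!duplicated(paste(edges$from, edges$to)), ]
  # nodes with only inhibiting parents stay silent; give them one activator
  for (j in (n_in + 1):n) {
    sel <- edges$to == nodes[j]
    if (!any(edges$sign[sel] == "->")) {
      edges$sign[which(sel)[1]] <- "->"
    }
  }
  edges$label <- paste0(edges$from, "_", edges$to)
  present <- unique(c(edges$from, edges$to))  # unused inputs drop out
  sinks <- setdiff(present, edges$from)
  net <- logic_network(edges, outputs = sinks)
  params <- random_params(net, contexts, inhibitor_range = c(0, 1))
  conds <- tibble::as_tibble(
    stats::setNames(as.list(round(stats::runif(length(input_nodes(net))), 3)),
                    input_nodes(net))
  )
  conds <- dplyr::bind_rows(conds, conds * 0, conds * 0 + 1)
  conds <- dplyr::bind_cols(
    tibble::tibble(condition = paste0("c", 1:3)), conds
  )
  list(network = net, params = params, conditions = conds)
}

# Noise-free/noisy two-context chain datasets from a seeded ground truth.
chain_case <- function(seed, n_diffs = 0, noise = 0,
                       contexts = c("X", "Y")) {
  net <- chain_network()
  truth <- generate_ground_truth(net, n_diffs, contexts = contexts,
                                 seed = seed, noise_scale = noise)
  datasets <- lapply(contexts, function(cx) {
    simulate_dataset(truth, chain_design(), cx)
  })
  list(network = net, truth = truth, datasets = datasets)
}

quick_config <- function(seed = 1, n_starts = 2, ...) {
  fit_config(n_starts = n_starts, seed = seed, ...)
}
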