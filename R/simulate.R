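# Compiled network representation used by the simulator and the fitter:
# nodes in topological order with per-node activator/inhibitor edge indices.
compile_network <- function(network) {
  ord <- topo_order(network)
  e <- network$edges
  from_i <- match(e$from, ord)
  to_i <- match(e$to, ord)
  act <- lapply(seq_along(ord), function(i) which(to_i == i & e$sign == "activating"))
  inh <- lapply(seq_along(ord), function(i) which(to_i == i & e$sign == "inhibiting"))
  list(
    nodes = ord,
    n = length(ord),
    input = ord %in% input_nodes(network),
    output = ord %in% output_nodes(network),
    from_i = from_i,
    to_i = to_i,
    act = act,
    inh = inh
  )
}

# Vectorized forward pass: one topological sweep over all conditions.
# inputs: matrix n_cond x n_inputs (named columns); w: per-edge weights.
# Returns activities plus the S (activation sum) and P (inhibition product)
# intermediates needed for backpropagation.
forward_pass <- function(cn, w, inputs) {
  nc <- nrow(inputs)
  A <- matrix(0, nc, cn$n, dimnames = list(NULL, cn$nodes))
  S <- matrix(0, nc, cn$n)
  P <- matrix(1, nc, cn$n)
  for (nm in colnames(inputs)) A[, nm] <- inputs[, nm]
  for (v in seq_len(cn$n)) {
    if (cn$input[v]) next
    ae <- cn$act[[v]]
    if (length(ae) == 0) next  # no activators, no basal term: activity 0
    s <- A[, cn$from_i[ae], drop = FALSE] %*% w[ae]
    p <- rep(1, nc)
    for (ie in cn$inh[[v]]) p <- p * (1 - w[ie] * A[, cn$from_i[ie]])
    S[, v] <- s
    P[, v] <- p
    A[, v] <- s * p
  }
  # guard against floating-point spill just past the unit interval
  A[A < 0] <- 0
  A[A > 1] <- 1
  list(A = A, S = S, P = P)
}

condition_matrix <- function(network, conditions) {
  ins <- input_nodes(network)
  conditions <- as_tibble(conditions)
  miss <- setdiff(ins, names(conditions))
  if (length(miss) > 0) {
    abort(paste0("condition table does not assign input node(s): ",
                 paste(miss, collapse = ", ")))
  }
  m <- as.matrix(conditions[, ins, drop = FALSE])
  if (anyNA(m) || any(m < 0 | m > 1)) abort("input assignments must be in [0, 1]")
  rownames(m) <- as.character(conditions$condition %||% seq_len(nrow(m)))
  m
}

#' Steady-state activities of a weighted logic network
#'
#' Propagates a condition's fixed input activities through the network in
#' topological order. A node with activating parents \eqn{u} (weights
#' \eqn{w_u}, summing to 1 over the node's activators) and inhibiting parents
#' \eqn{i} (weights \eqn{w_i \in [0,1]}) takes the activity
#' \deqn{a_v = \Big(\sum_u w_u a_u\Big) \prod_i (1 - w_i a_i),}
#' the probabilistic non-competitive-OR activation attenuated by independent
#' inhibition. On an acyclic network one topological sweep is the exact fixed
#' point of this update, so the result is independent of initialization; a
#' node with no activators (and no fixed input) has activity 0.
#'
#' @param network A [logic_network()].
#' @param params A [param_set()] (or plain data frame with label/context/value).
#' @param condition One-row data frame assigning every input node (plus an
#'   optional `condition` name column), or a named list/vector.
#' @param context Context whose parameter values to use.
#' @return Tibble with columns `node`, `role`, `activity`.
#' @examples
#' net <- logic_network(data.frame(from = "A", to = "B", sign = "->"),
#'                      outputs = "B")
#' prm <- param_set(tibble::tibble(label = character(), context = character(),
#'                                 value = numeric()))
#' steady_state(net, prm, c(A = 0.7), context = "ctx")
#' @export
steady_state <- function(network, params, condition, context) {
  if (!is.data.frame(condition)) {
    condition <- as_tibble(as.list(condition))
  }
  if (!"condition" %in% names(condition)) condition$condition <- "cond"
  cn <- compile_network(network)
  w <- edge_weights(network, params, context)
  fw <- forward_pass(cn, w, condition_matrix(network, condition))
  tibble(
    node = cn$nodes,
    role = network$nodes$role[match(cn$nodes, network$nodes$node)],
    activity = unname(fw$A[1, ])
  )
}

#' Simulate all conditions of a design
#'
#' Runs [steady_state()] for every row of a condition table and returns the
#' measured (output-node) activities, one row per condition.
#'
#' @inheritParams steady_state
#' @param conditions Data frame: `condition` column plus one column per
#'   input node (as in [measurement_set()]).
#' @return Tibble: `condition` column plus one column per output node.
#' @export
simulate_design <- function(network, params, conditions, context) {
  conditions <- as_tibble(conditions)
  if (!"condition" %in% names(conditions)) {
    conditions$condition <- paste0("c", seq_len(nrow(conditions)))
  }
  cn <- compile_network(network)
  w <- edge_weights(network, params, context)
  fw <- forward_pass(cn, w, condition_matrix(network, conditions))
  out <- fw$A[, cn$output, drop = FALSE]
  dplyr::bind_cols(
    tibble(condition = as.character(conditions$condition)),
    as_tibble(out)
  )
}
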