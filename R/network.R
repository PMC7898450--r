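#' Build a logic network from an edge table
#'
#' A `logic_network` is a signed, directed, acyclic interaction graph. Each
#' node has a role: `input` (activity fixed by the experimental condition:
#' growth-factor stimulators and drug-inhibitor nodes), `output` (measured
#' read-out, e.g. a phosphoprotein ratio) or `hidden`. Each edge is either
#' activating (`->`) or inhibiting (`-|`) and carries a parameter label;
#' edges sharing a label share a weight.
#'
#' Roles are inferred unless given explicitly: nodes without incoming edges
#' become inputs; `outputs` (or a `roles` table) declares the measured nodes;
#' everything else is hidden. When no outputs are declared, sink nodes are
#' taken as outputs.
#'
#' @param edges Data frame with columns `from`, `to`, `sign`
#'   (`"activating"`/`"inhibiting"`, or the tokens `"->"`/`"-|"`) and
#'   optionally `label` (defaults to `"<from>_<to>"`).
#' @param outputs Character vector of measured node names (optional).
#' @param roles Optional data frame with columns `node`, `role` overriding
#'   inference for the listed nodes; its row order fixes the node order.
#' @return An object of class `logic_network` with tibble components `nodes`
#'   (`node`, `role`) and `edges` (`from`, `to`, `sign`, `label`).
#' @examples
#' net <- logic_network(
#'   data.frame(from = c("S", "S"), to = c("A", "B"), sign = "->"),
#'   outputs = c("A", "B")
#' )
#' net
#' @export
logic_network <- function(edges, outputs = NULL, roles = NULL) {
  edges <- as_tibble(edges)
  required <- c("from", "to", "sign")
  if (!all(required %in% names(edges))) {
    abort(paste0("`edges` must have columns ", paste(required, collapse = ", ")))
  }
  edges$sign <- canonical_sign(edges$sign)
  if (!"label" %in% names(edges)) {
    edges$label <- paste0(edges$from, "_", edges$to)
  }
  edges <- edges[, c("from", "to", "sign", "label")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$label <- as.character(edges$label)

  if (any(edges$from == edges$to)) {
    bad <- edges$from[edges$from == edges$to][1]
    abort(paste0("self-loop on node '", bad, "' is not allowed"))
  }
  key <- paste(edges$from, edges$to)
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    abort(paste0("duplicated edge: ", sub(" ", " -> ", bad)))
  }

  node_names <- unique(c(edges$from, edges$to))
  if (!is.null(roles)) {
    roles <- as_tibble(roles)
    if (!all(c("node", "role") %in% names(roles))) {
      abort("`roles` must have columns node, role")
    }
    unknown <- setdiff(roles$node, node_names)
    if (length(unknown) > 0) {
      abort(paste0("role declared for unknown node(s): ",
                   paste(unknown, collapse = ", ")))
    }
    node_names <- unique(c(roles$node, node_names))
  }

  has_in <- node_names %in% edges$to
  has_out <- node_names %in% edges$from
  role <- ifelse(!has_in, "input", ifelse(!has_out, "output", "hidden"))
  names(role) <- node_names
  if (!is.null(outputs)) {
    # explicit outputs replace the sink heuristic entirely
    role[role == "output"] <- "hidden"
    unknown <- setdiff(outputs, node_names)
    if (length(unknown) > 0) {
      abort(paste0("output node(s) not in network: ",
                   paste(unknown, collapse = ", ")))
    }
    role[outputs] <- "output"
  }
  if (!is.null(roles)) {
    ok <- roles$role %in% c("input", "hidden", "output")
    if (!all(ok)) abort("roles must be one of input, hidden, output")
    role[roles$node] <- roles$role
  }
  if (any(role == "input" & has_in)) {
    bad <- node_names[role == "input" & has_in][1]
    abort(paste0("input node '", bad, "' has incoming edges"))
  }

  net <- structure(
    list(
      nodes = tibble(node = node_names, role = unname(role[node_names])),
      edges = edges
    ),
    class = "logic_network"
  )
  validate_network(net)
}

canonical_sign <- function(sign) {
  out <- dplyr::case_match(
    as.character(sign),
    c("->", "activating", "activates", "1") ~ "activating",
    c("-|", "inhibiting", "inhibits", "-1") ~ "inhibiting",
    .default = NA_character_
  )
  if (anyNA(out)) {
    abort(paste0("unknown sign token: '", as.character(sign)[is.na(out)][1],
                 "' (expected '->' or '-|')"))
  }
  out
}

# Structural validation: acyclicity (reporting one cycle on failure),
# endpoint existence and output reachability from the inputs.
validate_network <- function(net) {
  nodes <- net$nodes$node
  missing <- setdiff(c(net$edges$from, net$edges$to), nodes)
  if (length(missing) > 0) {
    abort(paste0("edge endpoint(s) not in node list: ",
                 paste(missing, collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    abort(paste0("network contains a cycle: ",
                 paste(find_cycle(net$edges), collapse = " -> ")))
  }
  # labels are weight-sharing groups; a label spanning several target nodes
  # cannot be normalized consistently on each node's simplex
  by_label <- split(net$edges$to, net$edges$label)
  multi_target <- names(by_label)[vapply(by_label, function(x) length(unique(x)) > 1, logical(1))]
  if (length(multi_target) > 0) {
    abort(paste0("parameter label(s) shared across different target nodes: ",
                 paste(multi_target, collapse = ", ")))
  }
  sign_by_label <- split(net$edges$sign, net$edges$label)
  mixed <- names(sign_by_label)[vapply(sign_by_label, function(x) length(unique(x)) > 1, logical(1))]
  if (length(mixed) > 0) {
    abort(paste0("parameter label(s) used with both signs: ",
                 paste(mixed, collapse = ", ")))
  }
  inputs <- nodes[net$nodes$role == "input"]
  outputs <- nodes[net$nodes$role == "output"]
  if (length(outputs) == 0) abort("network has no output node")
  if (length(inputs) == 0) abort("network has no input node")
  reach <- unique(names(unlist(igraph::neighborhood(
    g, order = length(nodes), nodes = inputs, mode = "out"
  ))))
  unreachable <- setdiff(outputs, reach)
  if (length(unreachable) > 0) {
    abort(paste0("output node(s) unreachable from any input: ",
                 paste(unreachable, collapse = ", ")))
  }
  net
}

# Depth-first search returning one directed cycle (node sequence, closed).
find_cycle <- function(edges) {
  adj <- split(edges$to, edges$from)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  res <- NULL
  visit <- function(v) {
    if (!is.null(res)) return()
    st <- state[[v]] %||% "new"
    if (st == "active") {
      i <- match(v, path)
      res <<- c(path[i:length(path)], v)
      return()
    }
    if (st == "done") return()
    state[[v]] <- "active"
    path <<- c(path, v)
    for (w in adj[[v]] %||% character(0)) visit(w)
    path <<- path[-length(path)]
    state[[v]] <- "done"
  }
  for (v in unique(edges$from)) visit(v)
  res
}

#' Topological order of a logic network
#'
#' @param network A [logic_network()].
#' @return Character vector of node names such that every edge points from an
#'   earlier to a later node.
#' @export
topo_order <- function(network) {
  stopifnot(inherits(network, "logic_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = network$nodes$node)
  )
  names(igraph::topo_sort(g, mode = "out"))
}

#' @export
print.logic_network <- function(x, ...) {
  counts <- table(factor(x$nodes$role, levels = c("input", "hidden", "output")))
  cat("<logic_network> ", nrow(x$nodes), " nodes (",
      counts[["input"]], " input, ", counts[["hidden"]], " hidden, ",
      counts[["output"]], " output), ", nrow(x$edges), " edges\n", sep = "")
  sym <- ifelse(x$edges$sign == "activating", "->", "-|")
  shown <- head(paste0("  ", x$edges$from, " ", sym, " ", x$edges$to,
                       "  [", x$edges$label, "]"), 12)
  cat(shown, sep = "\n")
  if (nrow(x$edges) > 12) cat("  ... and", nrow(x$edges) - 12, "more edges\n")
  invisible(x)
}

#' @rdname logic_network
#' @param x Object to query.
#' @export
input_nodes <- function(x) x$nodes$node[x$nodes$role == "input"]

#' @rdname logic_network
#' @export
output_nodes <- function(x) x$nodes$node[x$nodes$role == "output"]

#' Read / write an interaction-list network file
#'
#' The file dialect is tab-separated UTF-8 with `#` comment lines and a header
#' `source  sign  target  param_label`; sign tokens are `->` (activating) and
#' `-|` (inhibiting). An optional `[roles]` section lists `node  role` pairs
#' and overrides role inference. This is the same interaction-list layout
#' used by prior-knowledge network definitions for logic-model toolboxes, so
#' externally curated lists can be loaded directly.
#'
#' @param file Path to the network file (or, for `parse_network`, a character
#'   vector of lines).
#' @param outputs Optional character vector naming measured nodes (used when
#'   the file has no `[roles]` section).
#' @return `read_network`/`parse_network` return a [logic_network()];
#'   `write_network` returns `file` invisibly.
#' @export
read_network <- function(file, outputs = NULL) {
  parse_network(readLines(file, warn = FALSE), outputs = outputs)
}

#' @rdname read_network
#' @param lines Character vector: lines of an interaction-list document.
#' @export
parse_network <- function(lines, outputs = NULL) {
  lines_raw <- lines
  keep <- !grepl("^\\s*(#|$)", lines_raw)
  lineno <- which(keep)
  lines <- trimws(lines_raw[keep], which = "right")
  roles_at <- which(lines == "[roles]")
  if (length(roles_at) > 1) abort("multiple [roles] sections")
  if (length(roles_at) == 1) {
    edge_lines <- lines[seq_len(roles_at - 1)]
    edge_lineno <- lineno[seq_len(roles_at - 1)]
    role_lines <- lines[-seq_len(roles_at)]
  } else {
    edge_lines <- lines
    edge_lineno <- lineno
    role_lines <- character(0)
  }
  if (length(edge_lines) < 2) abort("network document has no edge rows")
  header <- strsplit(edge_lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("source", "sign", "target", "param_label")
  if (!identical(header[seq_along(expected)], expected)) {
    abort(paste0("expected header '", paste(expected, collapse = "\\t"), "'"))
  }
  fields <- strsplit(edge_lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("line ", edge_lineno[-1][nf < 3][1],
                 ": expected at least 3 tab-separated fields"))
  }
  sign_raw <- vapply(fields, `[[`, character(1), 2)
  bad <- !sign_raw %in% c("->", "-|")
  if (any(bad)) {
    abort(paste0("line ", edge_lineno[-1][bad][1], ": unknown sign token '",
                 sign_raw[bad][1], "'"))
  }
  edges <- tibble(
    from = vapply(fields, `[[`, character(1), 1),
    to = vapply(fields, `[[`, character(1), 3),
    sign = sign_raw,
    label = vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, character(1))
  )
  edges$label[is.na(edges$label)] <- paste0(edges$from, "_", edges$to)[is.na(edges$label)]
  roles <- NULL
  if (length(role_lines) > 0) {
    rf <- strsplit(role_lines, "\t", fixed = TRUE)
    if (any(lengths(rf) != 2)) abort("[roles] lines must be 'node\\trole'")
    roles <- tibble(
      node = vapply(rf, `[[`, character(1), 1),
      role = vapply(rf, `[[`, character(1), 2)
    )
  }
  logic_network(edges, outputs = outputs, roles = roles)
}

#' @rdname read_network
#' @param network A [logic_network()].
#' @export
write_network <- function(network, file) {
  stopifnot(inherits(network, "logic_network"))
  sym <- ifelse(network$edges$sign == "activating", "->", "-|")
  lines <- c(
    "source\tsign\ttarget\tparam_label",
    paste(network$edges$from, sym, network$edges$to, network$edges$label,
          sep = "\t"),
    "[roles]",
    paste(network$nodes$node, network$nodes$role, sep = "\t")
  )
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}
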