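#' Parameter sets: per-context edge weights with sharing structure
#'
#' A `param_set` is a tibble with one row per (parameter label, context)
#' giving the weight of the labelled edge(s) in that context, plus a `group`
#' column encoding the sharing structure: rows with the same group id are
#' constrained to an identical value (a label tied across all contexts uses
#' the label itself as group id; an untied row uses `"<label>@<context>"`).
#'
#' Only *free* labels appear: weights of activating edges into nodes with at
#' least two activators (which live on a per-node simplex summing to 1) and
#' weights of inhibiting edges (independently in \[0, 1\]). The weight of the
#' single activating edge into a one-activator node is structurally 1 and is
#' implied rather than stored.
#'
#' @param values Data frame with columns `label`, `context`, `value` and
#'   optionally `group`.
#' @param network Optional [logic_network()]; when given, labels are checked
#'   against the network's free labels and simplex sums are validated.
#' @return An object of classes `param_set`/`tbl_df`.
#' @export
param_set <- function(values, network = NULL) {
  df <- as_tibble(values)
  need <- c("label", "context", "value")
  if (!all(need %in% names(df))) {
    abort("`values` must have columns label, context, value")
  }
  if (!"group" %in% names(df)) {
    df$group <- paste0(df$label, "@", df$context)
  }
  df <- df[, c("label", "context", "value", "group")]
  df$label <- as.character(df$label)
  df$context <- as.character(df$context)
  df$group <- as.character(df$group)
  if (anyDuplicated(paste(df$label, df$context))) {
    abort("duplicate (label, context) rows")
  }
  if (any(!is.finite(df$value)) || any(df$value < -1e-9 | df$value > 1 + 1e-9)) {
    abort("parameter values must lie in [0, 1]")
  }
  df$value <- pmin(1, pmax(0, df$value))
  rng <- vapply(split(df$value, df$group), function(v) max(v) - min(v), numeric(1))
  if (any(rng > 1e-8)) {
    abort(paste0("values differ within sharing group(s): ",
                 paste(names(rng)[rng > 1e-8], collapse = ", ")))
  }
  if (!is.null(network)) {
    fl <- free_labels(network)
    unknown <- setdiff(df$label, fl$label)
    if (length(unknown) > 0) {
      abort(paste0("label(s) not free parameters of the network: ",
                   paste(unknown, collapse = ", ")))
    }
    missing <- setdiff(fl$label, df$label)
    if (length(missing) > 0) {
      abort(paste0("missing label(s): ", paste(missing, collapse = ", ")))
    }
    for (ctx in unique(df$context)) {
      w <- edge_weights(network, df, ctx, .validate = FALSE)
      check_simplex(network, w, ctx)
    }
  }
  class(df) <- c("param_set", class(df))
  df
}

#' Free parameter labels of a network
#'
#' @param network A [logic_network()].
#' @return Tibble with columns `label`, `type` (`"activator"`/`"inhibitor"`)
#'   and `target` (the node the labelled edges point at).
#' @export
free_labels <- function(network) {
  e <- network$edges
  n_act <- table(e$to[e$sign == "activating"])
  multi <- names(n_act)[n_act >= 2]
  free <- e[(e$sign == "activating" & e$to %in% multi) | e$sign == "inhibiting", ]
  out <- dplyr::distinct(
    tibble(
      label = free$label,
      type = ifelse(free$sign == "activating", "activator", "inhibitor"),
      target = free$to
    )
  )
  out[order(match(out$label, e$label)), ]
}

# Per-edge weight vector for one context (order of network$edges).
# Single-activator edges are 1; free edges look their label up in `params`.
edge_weights <- function(network, params, context, .validate = TRUE) {
  e <- network$edges
  fl <- free_labels(network)
  w <- rep(1, nrow(e))
  is_free <- e$label %in% fl$label
  p <- params[params$context == context, ]
  if (any(is_free)) {
    idx <- match(e$label[is_free], p$label)
    if (anyNA(idx)) {
      abort(paste0("no value for label(s) ",
                   paste(unique(e$label[is_free][is.na(idx)]), collapse = ", "),
                   " in context '", context, "'"))
    }
    w[is_free] <- p$value[idx]
  }
  if (.validate) check_simplex(network, w, context)
  w
}

check_simplex <- function(network, w, context, tol = 1e-6) {
  e <- network$edges
  act <- e$sign == "activating"
  sums <- tapply(w[act], e$to[act], sum)
  multi <- names(which(table(e$to[act]) >= 2))
  bad <- names(sums)[names(sums) %in% multi & abs(sums - 1) > tol]
  if (length(bad) > 0) {
    abort(paste0("activator weights do not sum to 1 at node(s) ",
                 paste(bad, collapse = ", "), " (context '", context, "')"))
  }
  invisible(w)
}

#' Count distinct model parameters under a merge tolerance
#'
#' A label whose values agree across contexts (standard deviation below
#' `merge_tol`) counts once; a context-specific label counts once per
#' context, since each context carries a free value for it. This is the
#' effective parameter count `k` used in the BIC.
#'
#' @param params A [param_set()].
#' @param merge_tol Nonnegative SD threshold below which a label is
#'   considered uniform across contexts.
#' @return Integer `k`.
#' @export
count_distinct_parameters <- function(params, merge_tol = 0.01) {
  stopifnot(merge_tol >= 0)
  n_ctx <- length(unique(params$context))
  sds <- label_context_sd(params)
  uniform <- sds < merge_tol | n_ctx == 1
  as.integer(sum(uniform) + n_ctx * sum(!uniform))
}

# Per-label SD of the value across contexts (0 for a single context).
label_context_sd <- function(params) {
  vapply(split(params$value, factor(params$label, levels = unique(params$label))),
         function(v) if (length(v) < 2) 0 else sd(v), numeric(1))
}

#' Draw a random valid parameter set
#'
#' Activator weights are drawn uniformly on each node's simplex (flat
#' Dirichlet over that node's activating edges) and inhibitor weights
#' uniformly on \[`inhibitor_range`\]. All contexts share the same values.
#'
#' @param network A [logic_network()].
#' @param contexts Character vector of context names.
#' @param inhibitor_range Length-2 numeric range for inhibitor weights.
#' @return A [param_set()] (group = label: all contexts tied).
#' @export
random_params <- function(network, contexts,
                          inhibitor_range = c(0.5, 1)) {
  fl <- free_labels(network)
  e <- network$edges
  vals <- setNames(numeric(nrow(fl)), fl$label)
  for (node in unique(fl$target[fl$type == "activator"])) {
    labs <- unique(e$label[e$sign == "activating" & e$to == node])
    # flat Dirichlet over the node's activator edges, averaged per label
    per_edge <- rexp(sum(e$sign == "activating" & e$to == node))
    per_edge <- per_edge / sum(per_edge)
    edge_lab <- e$label[e$sign == "activating" & e$to == node]
    vals[labs] <- tapply(per_edge, factor(edge_lab, levels = labs), sum) /
      as.numeric(table(factor(edge_lab, levels = labs)))
  }
  inh <- fl$label[fl$type == "inhibitor"]
  vals[inh] <- runif(length(inh), inhibitor_range[1], inhibitor_range[2])
  grid <- tidyr::expand_grid(label = fl$label, context = contexts)
  param_set(
    tibble(label = grid$label, context = grid$context,
           value = vals[grid$label], group = grid$label),
    network = network
  )
}
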