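#' Literature-style prior network upstream of L-plastin Ser5 phosphorylation
#'
#' A packaged rendering of the candidate signalling network used throughout
#' the package's examples: growth-factor stimulators (EGF, HGF, IGF, PMA)
#' and kinase-inhibitor drugs (BID = RSK inhibitor Bi-D1870, AKTi = AKT
#' inhibitor VIII, FAKi = FAK inhibitor II, MEKi = Trametinib, PI3KmTORi =
#' the dual PI3K/mTOR inhibitor Apitolisib) act as input nodes; the
#' Ras/Raf/MEK/ERK/RSK cascade and the PI3K/PDK1/(AKT, SGK)/mTOR axis carry
#' the signal, with FAK and Src as cross-talk hubs and PKA/PKC as additional
#' kinases; ERK, AKT, Src and LPL (Ser5-phosphorylated L-plastin) are the
#' measured outputs. LPL receives exactly five activating edges, from RSK,
#' SGK, PKA, PKC and p70S6K. Drug nodes act through inhibiting edges onto
#' their targets and are set to 1 when the drug is applied.
#'
#' This fixture is a synthetic, literature-style reconstruction; externally
#' curated interaction lists in the same dialect load through
#' [read_network()] for exact replication work.
#'
#' @return A [logic_network()].
#' @examples
#' net <- lplastin_prior_network()
#' sum(net$edges$to == "LPL")
#' @export
lplastin_prior_network <- function() {
  act <- function(from, to) tibble(from = from, to = to, sign = "activating")
  inh <- function(from, to) tibble(from = from, to = to, sign = "inhibiting")
  edges <- dplyr::bind_rows(
    act("EGF", "EGFR"), act("HGF", "HGFR"), act("IGF", "IGFR"),
    act("EGFR", "Ras"), act("HGFR", "Ras"), act("Src", "Ras"),
    act("EGFR", "PI3K"), act("HGFR", "PI3K"), act("IGFR", "PI3K"),
    act("Src", "PI3K"),
    act("EGFR", "FAK"), act("HGFR", "FAK"),
    act("FAK", "Src"),
    act("Ras", "Raf"), act("PKC", "Raf"),
    act("Raf", "MEK"), act("MEK", "ERK"), act("ERK", "RSK"),
    act("PI3K", "PDK1"), act("PI3K", "mTORC2"),
    act("PDK1", "AKT"), act("mTORC2", "AKT"),
    act("PDK1", "SGK"), act("mTORC2", "SGK"),
    act("AKT", "mTORC1"),
    act("mTORC1", "p70S6K"),
    act("PMA", "PKC"),
    act("EGFR", "PKA"),
    act("RSK", "LPL"), act("SGK", "LPL"), act("PKA", "LPL"),
    act("PKC", "LPL"), act("p70S6K", "LPL"),
    inh("BID", "RSK"), inh("AKTi", "AKT"), inh("FAKi", "FAK"),
    inh("MEKi", "MEK"), inh("PI3KmTORi", "PI3K"),
    inh("PI3KmTORi", "mTORC1"), inh("PI3KmTORi", "mTORC2")
  )
  edges$label <- paste0(edges$from, "_", edges$to)
  logic_network(edges, outputs = c("ERK", "AKT", "Src", "LPL"))
}

#' Experimental design of the perturbation study
#'
#' Enumerates the stimulation/inhibition conditions used for model
#' contextualization: a serum-starved control, each stimulator alone, each
#' of the three modelling inhibitors (BID, AKTi, FAKi) alone, and every
#' inhibitor + stimulator pair — 20 conditions for BT-20, HCC38 and SKBR3.
#' MCF7 cells lack detectable EGFR and HGFR, so their EGF and HGF arms are
#' absent: 12 conditions. The validation drugs (MEKi = Trametinib,
#' PI3KmTORi = Apitolisib) are carried as always-off inputs.
#'
#' @param context One of `"BT-20"`, `"HCC38"`, `"MCF7"`, `"SKBR3"`.
#' @return Tibble: `condition` column plus one 0/1 column per input node of
#'   [lplastin_prior_network()].
#' @examples
#' nrow(paper_design("MCF7"))
#' nrow(paper_design("BT-20"))
#' @export
paper_design <- function(context) {
  contexts <- c("BT-20", "HCC38", "MCF7", "SKBR3")
  if (!is.character(context) || length(context) != 1 || !context %in% contexts) {
    abort(paste0("`context` must be one of ",
                 paste(contexts, collapse = ", ")))
  }
  stims <- if (context == "MCF7") c("IGF", "PMA") else c("EGF", "HGF", "IGF", "PMA")
  inhs <- c("BID", "AKTi", "FAKi")
  rows <- c(
    list(c(name = "CTRL")),
    lapply(stims, function(s) c(name = s, setNames(1, s))),
    lapply(inhs, function(i) c(name = i, setNames(1, i))),
    unlist(lapply(inhs, function(i) {
      lapply(stims, function(s) {
        c(name = paste0(i, "+", s), setNames(1, i), setNames(1, s))
      })
    }), recursive = FALSE)
  )
  all_inputs <- input_nodes(lplastin_prior_network())
  df <- purrr::map_dfr(rows, function(r) {
    vals <- setNames(as.list(rep(0, length(all_inputs))), all_inputs)
    for (nm in setdiff(names(r), "name")) vals[[nm]] <- as.numeric(r[[nm]])
    dplyr::bind_cols(tibble(condition = unname(r[["name"]])), as_tibble(vals))
  })
  df
}

#' Small identifiable branched-chain fixture
#'
#' A seven-node network used in recovery experiments: stimulators S1, S2,
#' inhibitor drugs I1, I2, a hidden integrator M with two activators (an
#' identifiable simplex pair), and outputs B (inhibited by I1) and C (a
#' second simplex pair, inhibited by I2). All five free labels are
#' identifiable under the full-factorial design of [chain_design()].
#'
#' @return A [logic_network()].
#' @export
chain_network <- function() {
  edges <- tibble(
    from = c("S1", "S2", "M", "I1", "M", "S2", "I2"),
    to   = c("M", "M", "B", "B", "C", "C", "C"),
    sign = c("->", "->", "->", "-|", "->", "->", "-|")
  )
  edges$label <- paste0(edges$from, "_", edges$to)
  logic_network(edges, outputs = c("B", "C"))
}

#' @rdname chain_network
#' @return `chain_design()`: tibble with the 16-condition full factorial of
#'   the four inputs.
#' @export
chain_design <- function() {
  g <- tidyr::expand_grid(S1 = c(0, 1), S2 = c(0, 1), I1 = c(0, 1), I2 = c(0, 1))
  dplyr::bind_cols(
    tibble(condition = paste0("c", seq_len(nrow(g)))),
    g
  )
}

#' Generate a ground-truth parameterization with known context differences
#'
#' Draws one shared random valid parameter set (see [random_params()]) and
#' then makes `n_context_diffs` labels context-specific by shifting their
#' value in one (distinct) context by at least 0.2. By default only labels
#' whose value can move independently — inhibitor-edge weights — are
#' eligible: perturbing one coordinate of an activator simplex necessarily
#' drags its siblings along, which would blur the sharing structure.
#' Activator labels can be made eligible explicitly; the renormalization is
#' then applied to the whole node simplex.
#'
#' @param network A [logic_network()].
#' @param n_context_diffs Number of labels to make context-specific.
#' @param contexts Character vector of context names.
#' @param seed Integer seed.
#' @param noise_scale Measurement noise SD recorded in the truth (used by
#'   [simulate_dataset()]).
#' @param eligible Optional character vector of labels eligible for
#'   perturbation (default: the network's inhibitor labels).
#' @return Object of class `ground_truth`: list with `network`, `params`
#'   (a [param_set()]), `context_diffs` (tibble `label`, `context`),
#'   `noise_scale`, `seed`.
#' @export
generate_ground_truth <- function(network, n_context_diffs = 0, contexts,
                                  seed = 1, noise_scale = 0.05,
                                  eligible = NULL) {
  fl <- free_labels(network)
  if (is.null(eligible)) eligible <- fl$label[fl$type == "inhibitor"]
  unknown <- setdiff(eligible, fl$label)
  if (length(unknown) > 0) {
    abort(paste0("eligible label(s) not free in the network: ",
                 paste(unknown, collapse = ", ")))
  }
  if (n_context_diffs > length(eligible)) {
    abort("`n_context_diffs` exceeds the number of eligible labels")
  }
  set.seed(seed)
  params <- random_params(network, contexts)
  diffs <- tibble(label = character(0), context = character(0))
  if (n_context_diffs > 0) {
    labs <- sample(eligible, n_context_diffs)
    for (lab in labs) {
      ctx <- sample(contexts, 1)
      type <- fl$type[fl$label == lab]
      done <- FALSE
      for (attempt in 1:100) {
        row <- params$label == lab & params$context == ctx
        old <- params$value[row][1]
        delta <- runif(1, 0.2, 0.4) * sample(c(-1, 1), 1)
        new <- old + delta
        if (type == "inhibitor") {
          if (new >= 0 && new <= 1) {
            params$value[row] <- new
            params$group[row] <- paste0(lab, "@", ctx)
            done <- TRUE
            break
          }
        } else {
          node <- fl$target[fl$label == lab]
          sibs <- params$label %in%
            fl$label[fl$type == "activator" & fl$target == node] &
            params$context == ctx
          v <- params$value[sibs]
          names(v) <- params$label[sibs]
          if (new > 0 && new < 1) {
            rest <- setdiff(names(v), lab)
            v[rest] <- v[rest] * (1 - new) / sum(v[rest])
            v[lab] <- new
            params$value[sibs] <- v[params$label[sibs]]
            params$group[sibs] <- paste0(params$label[sibs], "@", ctx)
            done <- TRUE
            break
          }
        }
      }
      if (!done) {
        abort(paste0("could not perturb label '", lab,
                     "' after 100 attempts"))
      }
      diffs <- dplyr::bind_rows(diffs, tibble(label = lab, context = ctx))
    }
    # untouched (label, context) pairs of perturbed labels keep per-label
    # groups only where all remaining contexts still agree
    params <- param_set(params[, c("label", "context", "value", "group")],
                        network = network)
  }
  structure(
    list(network = network, params = params, context_diffs = diffs,
         noise_scale = noise_scale, seed = seed),
    class = "ground_truth"
  )
}

#' Practically identifiable parameter labels of a ground truth
#'
#' A parameter is practically identifiable under a design only if changing
#' it changes the simulated outputs appreciably. For each free label this
#' computes a central-difference sensitivity of the output activities to the
#' label's weight (redistributing the complementary mass proportionally over
#' the node's other activators for simplex labels) and keeps labels whose
#' root-mean-square output response per unit weight, maximized over
#' contexts, is at least `min_sensitivity`. Near-collinear activator splits
#' (e.g. two parents carrying almost identical signals) fall below the
#' threshold and are excluded from recovery comparisons.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param design Condition table.
#' @param contexts Contexts to evaluate (default: those of the truth).
#' @param min_sensitivity Threshold on the RMS output response.
#' @param h Half-width of the weight perturbation.
#' @return Character vector of identifiable labels.
#' @export
identifiable_labels <- function(truth, design, contexts = NULL,
                                min_sensitivity = 0.1, h = 0.05) {
  stopifnot(inherits(truth, "ground_truth"))
  net <- truth$network
  fl <- free_labels(net)
  if (is.null(contexts)) contexts <- unique(truth$params$context)
  perturbed <- function(params, lab, ctx, delta) {
    p <- params
    row <- p$label == lab & p$context == ctx
    type <- fl$type[fl$label == lab]
    v <- p$value[row][1]
    new <- min(1, max(0, v + delta))
    if (type == "inhibitor") {
      p$value[row] <- new
    } else {
      node <- fl$target[fl$label == lab]
      sibs <- p$label %in% fl$label[fl$type == "activator" & fl$target == node] &
        p$context == ctx & !row
      rest <- sum(p$value[sibs])
      if (rest < 1e-12) return(NULL)
      p$value[sibs] <- p$value[sibs] * (1 - new) / rest
      p$value[row] <- new
    }
    p$group <- paste0(p$label, "@", p$context)
    p
  }
  sens <- vapply(fl$label, function(lab) {
    max(vapply(contexts, function(ctx) {
      up <- perturbed(truth$params, lab, ctx, h)
      dn <- perturbed(truth$params, lab, ctx, -h)
      if (is.null(up) || is.null(dn)) return(0)
      su <- as.matrix(simulate_design(net, up, design, ctx)[, -1])
      sv <- as.matrix(simulate_design(net, dn, design, ctx)[, -1])
      sqrt(mean((su - sv)^2)) / (2 * h)
    }, numeric(1)))
  }, numeric(1))
  fl$label[sens >= min_sensitivity]
}

#' Simulate a noisy dataset from a ground truth
#'
#' Runs [simulate_design()] under the truth's parameters and adds clipped
#' Gaussian noise of SD `truth$noise_scale`; the SEM columns record the
#' generating SD, so resampling experiments can reuse it.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param design Condition table (e.g. [chain_design()] or [paper_design()]).
#' @param context Context whose parameters to simulate.
#' @param seed Integer seed for the noise draw; defaults to a value derived
#'   from the truth seed and the context name.
#' @return A [measurement_set()].
#' @export
simulate_dataset <- function(truth, design, context, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(seed)) {
    seed <- truth$seed * 1000L + sum(utf8ToInt(context)) %% 1000L
  }
  sim <- simulate_design(truth$network, truth$params, design, context)
  out_cols <- setdiff(names(sim), "condition")
  vals <- as.matrix(sim[, out_cols, drop = FALSE])
  if (truth$noise_scale > 0) {
    set.seed(seed)
    vals <- pmin(pmax(vals + rnorm(length(vals), sd = truth$noise_scale), 0), 1)
  }
  values <- dplyr::bind_cols(sim["condition"], as_tibble(vals))
  sem <- values
  sem[out_cols] <- truth$noise_scale
  measurement_set(context, design, values, sem = sem,
                  network = truth$network)
}
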