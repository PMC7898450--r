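test_that("a minimal interaction list parses with inferred roles", {
  net <- parse_network(
    c("source\tsign\ttarget\tparam_label", "A\t->\tB\tkAB"),
    outputs = "B"
  )
  expect_s3_class(net, "logic_network")
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(input_nodes(net), "A")
  expect_equal(output_nodes(net), "B")
  expect_equal(net$edges$sign, "activating")
})

test_that("structural defects are rejected with informative errors", {
  hdr <- "source\tsign\ttarget\tparam_label"
  expect_error(
    parse_network(c(hdr, "A\t->\tB\tk1", "B\t->\tA\tk2")),
    "cycle"
  )
  expect_error(
    parse_network(c(hdr, "A\t=>\tB\tk1")),
    "line 2.*unknown sign"
  )
  expect_error(
    logic_network(data.frame(from = c("A", "A"), to = c("B", "B"),
                             sign = c("->", "-|"))),
    "duplicated edge"
  )
  expect_error(
    logic_network(data.frame(from = "A", to = "A", sign = "->")),
    "self-loop"
  )
  # a label tied to two different target nodes cannot share a weight
  expect_error(
    logic_network(data.frame(from = c("A", "A", "C"),
                             to = c("B", "C", "D"),
                             sign = "->",
                             label = c("k", "x", "k"))),
    "shared across different target nodes"
  )
})

test_that("outputs must be reachable from an input", {
  # B -| C is C's only in-edge, so C never activates, but it is reachable;
  # an isolated declared output is not
  expect_error(
    logic_network(
      data.frame(from = c("A", "D"), to = c("B", "E"), sign = "->"),
      outputs = "B",
      roles = data.frame(node = c("E"), role = "output")
    ),
    NA
  )
  expect_error(
    logic_network(
      data.frame(from = "A", to = "B", sign = "->"),
      outputs = "B",
      roles = data.frame(node = c("C", "A", "B"),
                         role = c("output", "input", "output"))
    ),
    "role declared for unknown node"
  )
})

test_that("network files round-trip through write and parse unchanged", {
  withr::with_seed(11, {
    for (s in 1:5) {
      case <- random_dag_case(s * 7)
      path <- withr::local_tempfile(fileext = ".tsv")
      write_network(case$network, path)
      back <- read_network(path)
      expect_identical(back$nodes, case$network$nodes)
      expect_identical(back$edges, case$network$edges)
    }
  })
})

test_that("the packaged L-plastin fixture matches its documented structure", {
  net <- lplastin_prior_network()
  into_lpl <- net$edges[net$edges$to == "LPL", ]
  expect_equal(nrow(into_lpl), 5)
  expect_true(all(into_lpl$sign == "activating"))
  expect_setequal(into_lpl$from, c("p70S6K", "PKA", "PKC", "RSK", "SGK"))
  expect_setequal(output_nodes(net), c("ERK", "AKT", "Src", "LPL"))
  expect_true(all(c("EGF", "HGF", "IGF", "PMA", "BID", "AKTi", "FAKi",
                    "MEKi", "PI3KmTORi") %in% input_nodes(net)))
  # acyclic by construction: topological order exists and respects edges
  ord <- topo_order(net)
  expect_true(all(match(net$edges$from, ord) < match(net$edges$to, ord)))
})

test_that("measurement tables parse, validate and round-trip", {
  net <- logic_network(data.frame(from = "A", to = "B", sign = "->"),
                       outputs = "B")
  tab <- tibble::tibble(condition = c("c1", "c2"), A = c(0, 1),
                        B = c(0.2, 0.9))
  ms <- parse_measurements(tab, net, "ctx")
  expect_equal(nrow(ms$conditions), 2)
  expect_equal(setdiff(names(ms$values), "condition"), "B")

  expect_error(
    parse_measurements(dplyr::mutate(tab, ERK = 0.5), net, "ctx"),
    "not input or output nodes"
  )
  expect_error(
    parse_measurements(tab[, c("condition", "B")], net, "ctx"),
    "missing input-node column"
  )
  expect_error(
    parse_measurements(dplyr::mutate(tab, B = c(0.2, 1.4)), net, "ctx"),
    "outside \\[0, 1\\]"
  )

  # generator output (20 conditions, 4 outputs, SEM columns) round-trips
  truth <- generate_ground_truth(lplastin_prior_network(), 0,
                                 contexts = "BT-20", seed = 3,
                                 noise_scale = 0.05)
  ds <- simulate_dataset(truth, paper_design("BT-20"), "BT-20")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(ds, path)
  back <- read_measurements(path, truth$network, "BT-20")
  expect_identical(back$context, ds$context)
  expect_equal(as.data.frame(back$conditions), as.data.frame(ds$conditions))
  expect_equal(as.data.frame(back$values), as.data.frame(ds$values))
  expect_equal(as.data.frame(back$sem), as.data.frame(ds$sem))
})

test_that("blot normalization follows ratio -> blot mean -> min-max", {
  # equal phospho and total: every stage degenerates to a constant
  flat <- normalize_blots(data.frame(blot = c(1, 1, 2), phospho = c(2, 2, 5),
                                     total = c(2, 2, 5)))
  expect_true(all(flat$ratio == 1))
  expect_true(all(flat$blot_norm == 1))
  expect_true(length(unique(flat$activity)) == 1)

  two <- normalize_blots(data.frame(blot = 1, phospho = c(2, 4),
                                    total = c(1, 1)))
  expect_equal(two$blot_norm, c(2 / 3, 4 / 3))
  expect_equal(two$activity, c(0, 1))

  # three blots against a hand-computed table:
  # ratios blot1: 1, 3 (mean 2 -> 0.5, 1.5); blot2: 2, 6 (mean 4 -> 0.5, 1.5);
  # blot3: 4 (mean 4 -> 1); min-max over {0.5, 1.5, 0.5, 1.5, 1}
  three <- normalize_blots(data.frame(
    blot = c(1, 1, 2, 2, 3),
    phospho = c(1, 3, 4, 12, 8),
    total = c(1, 1, 2, 2, 2)
  ))
  expect_equal(three$blot_norm, c(0.5, 1.5, 0.5, 1.5, 1))
  expect_equal(three$activity, c(0, 1, 0, 1, 0.5))

  expect_error(normalize_blots(data.frame(blot = 1, phospho = 1, total = 0)),
               "strictly positive")
})

test_that("blot normalization is invariant to per-blot intensity rescaling", {
  withr::with_seed(4, {
    base <- data.frame(
      blot = rep(1:3, each = 4),
      phospho = stats::runif(12, 0.5, 5),
      total = stats::runif(12, 0.5, 5)
    )
    scaled <- base
    gains <- c(10, 0.3, 2.5)[scaled$blot]
    scaled$phospho <- scaled$phospho * gains
    a <- normalize_blots(base)$activity
    b <- normalize_blots(scaled)$activity
    expect_equal(a, b, tolerance = 1e-12)
    expect_true(all(a >= 0 & a <= 1))
  })
})
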