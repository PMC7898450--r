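empty_params <- function() {
  param_set(tibble::tibble(label = character(), context = character(),
                           value = numeric()))
}

test_that("activation propagates identically through a single-activator edge", {
  net <- logic_network(data.frame(from = "A", to = "B", sign = "->"),
                       outputs = "B")
  st <- steady_state(net, empty_params(), c(A = 0.7), "ctx")
  expect_equal(st$activity[st$node == "B"], 0.7)
})

test_that("a full-strength inhibitor silences its target completely", {
  net <- logic_network(
    data.frame(from = c("A", "I"), to = c("C", "C"), sign = c("->", "-|")),
    outputs = "C"
  )
  prm <- param_set(tibble::tibble(label = "I_C", context = "ctx", value = 1))
  st <- steady_state(net, prm, c(A = 1, I = 1), "ctx")
  expect_equal(st$activity[st$node == "C"], 0)
  # and releases it when absent
  st2 <- steady_state(net, prm, c(A = 1, I = 0), "ctx")
  expect_equal(st2$activity[st2$node == "C"], 1)
})

test_that("a node with inhibitors but no activators stays at zero", {
  net <- logic_network(
    data.frame(from = c("A", "I"), to = c("B", "C"), sign = c("->", "-|"),
               label = c("kb", "kc")),
    outputs = "B",
    roles = data.frame(node = "C", role = "hidden")
  )
  prm <- param_set(tibble::tibble(label = "kc", context = "ctx", value = 0.5))
  st <- steady_state(net, prm, c(A = 1, I = 1), "ctx")
  expect_equal(st$activity[st$node == "C"], 0)
})

test_that("chain fixture activities match hand-computed arithmetic", {
  net <- chain_network()
  prm <- param_set(tibble::tibble(
    label = c("S1_M", "S2_M", "I1_B", "M_C", "S2_C", "I2_C"),
    context = "ctx",
    value = c(0.3, 0.7, 0.8, 0.5, 0.5, 1)
  ), network = net)
  # S1=1, S2=1, I1=1, I2=0: M = 1, B = 1*(1-0.8), C = (0.5+0.5)*1
  st <- steady_state(net, prm, c(S1 = 1, S2 = 1, I1 = 1, I2 = 0), "ctx")
  a <- stats::setNames(st$activity, st$node)
  expect_equal(unname(a[c("M", "B", "C")]), c(1, 0.2, 1))
  # S1=0.5, S2=0, I1=0, I2=1: M = 0.15, B = 0.15, C = 0.075*(1-1) = 0
  st2 <- steady_state(net, prm, c(S1 = 0.5, S2 = 0, I1 = 0, I2 = 1), "ctx")
  a2 <- stats::setNames(st2$activity, st2$node)
  expect_equal(unname(a2[c("M", "B", "C")]), c(0.15, 0.15, 0))
})

test_that("topological evaluation equals the damped fixed-point oracle", {
  for (s in 1:20) {
    case <- random_dag_case(100 + s)
    for (i in seq_len(nrow(case$conditions))) {
      cond <- case$conditions[i, ]
      st <- steady_state(case$network, case$params, cond, "ctx")
      withr::with_seed(s, {
        orc <- oracle_steady_state(case$network, case$params, cond, "ctx",
                                   n_starts = 10)
      })
      for (r in seq_len(nrow(orc))) {
        expect_equal(stats::setNames(st$activity, st$node), orc[r, st$node],
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("activities always stay within the unit interval", {
  for (s in 1:15) {
    case <- random_dag_case(300 + s)
    sim <- simulate_design(case$network, case$params, case$conditions, "ctx")
    m <- as.matrix(sim[, -1])
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("raising an input never lowers downstream activity without inhibition", {
  for (s in 1:10) {
    case <- random_dag_case(500 + s)
    e <- case$network$edges
    if (any(e$sign == "inhibiting")) {
      e$sign <- "activating"
      e <- e[!duplicated(paste(e$from, e$to)), ]
      net <- tryCatch(
        logic_network(e, outputs = setdiff(case$network$nodes$node, e$from)),
        error = function(err) NULL
      )
      if (is.null(net)) next
      prm <- withr::with_seed(s, random_params(net, "ctx"))
    } else {
      net <- case$network
      prm <- case$params
    }
    ins <- input_nodes(net)
    lo <- tibble::as_tibble(stats::setNames(as.list(rep(0.2, length(ins))), ins))
    hi <- lo
    hi[[sample(ins, 1)]] <- 0.9
    lo$condition <- "lo"; hi$condition <- "hi"
    out_lo <- simulate_design(net, prm, lo, "ctx")
    out_hi <- simulate_design(net, prm, hi, "ctx")
    expect_true(all(as.matrix(out_hi[, -1]) >= as.matrix(out_lo[, -1]) - 1e-12))
  }
})

test_that("simulate_design is deterministic and row-wise consistent", {
  case <- random_dag_case(42)
  conds <- dplyr::bind_rows(case$conditions, case$conditions[1, ])
  conds$condition <- paste0("c", seq_len(nrow(conds)))
  sim <- simulate_design(case$network, case$params, conds, "ctx")
  expect_identical(unlist(sim[1, -1]), unlist(sim[nrow(sim), -1]))
  sim2 <- simulate_design(case$network, case$params, conds, "ctx")
  expect_identical(sim, sim2)
  # single condition equals the steady-state restriction
  st <- steady_state(case$network, case$params, case$conditions[1, ], "ctx")
  outs <- st$node[st$role == "output"]
  expect_equal(unlist(sim[1, outs]),
               stats::setNames(st$activity[match(outs, st$node)], outs))
})

test_that("invalid parameters and unassigned inputs are rejected", {
  net <- chain_network()
  ok <- param_set(tibble::tibble(
    label = c("S1_M", "S2_M", "I1_B", "M_C", "S2_C", "I2_C"),
    context = "ctx", value = c(0.3, 0.7, 0.8, 0.5, 0.5, 1)
  ), network = net)
  expect_error(
    steady_state(net, ok, c(S1 = 1), "ctx"),
    "does not assign input"
  )
  bad <- tibble::tibble(
    label = c("S1_M", "S2_M", "I1_B", "M_C", "S2_C", "I2_C"),
    context = "ctx", value = c(0.9, 0.9, 0.5, 0.5, 0.5, 0.5)
  )
  expect_error(param_set(bad, network = net), "sum to 1")
  expect_error(
    param_set(dplyr::mutate(bad, value = c(0.5, 0.5, 1.5, 0.5, 0.5, 0.5)),
              network = net),
    "\\[0, 1\\]"
  )
})
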