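# brute-force path enumeration oracle, independent of the DP implementation
brute_total_coupling <- function(graph, from) {
  total <- 0
  stack <- list(list(node = from, w = 1))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (cur$node == "dv") {
      total <- total + cur$w
      next
    }
    e <- graph$edges[graph$edges$from == cur$node, , drop = FALSE]
    for (i in seq_len(nrow(e)))
      stack[[length(stack) + 1L]] <-
        list(node = e$to[i], w = cur$w * e$weight[i])
  }
  total
}

random_dag <- function(n_iv, p_edge = 0.7) {
  nodes <- c("inp1", if (n_iv > 0) paste0("iv", seq_len(n_iv)), "dv")
  edges <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i || nodes[i] == "dv") next
    if (runif(1) < p_edge)
      edges[[length(edges) + 1L]] <- data.frame(
        from = nodes[i], to = nodes[j], weight = rnorm(1))
  }
  if (!length(edges))
    edges[[1]] <- data.frame(from = "inp1", to = "dv", weight = rnorm(1))
  graph_from_edges(nodes, do.call(rbind, edges))
}

test_that("path-sum total coupling equals brute-force enumeration", {
  set.seed(40)
  for (i in 1:20) {
    g <- random_dag(sample(0:4, 1))
    expect_equal(total_effective_coupling(g, "inp1"),
                 brute_total_coupling(g, "inp1"), tolerance = 1e-12)
  }
  # single edge
  g1 <- graph_from_edges(c("inp1", "dv"),
                         data.frame(from = "inp1", to = "dv", weight = 0.37))
  expect_equal(total_effective_coupling(g1), 0.37)
})

test_that("effective couplings of independent random vectors vanish", {
  set.seed(41)
  N <- 6000
  net <- network_params(rnorm(N), rnorm(N), rnorm(N), rnorm(N), rnorm(N),
                        m = cbind(rnorm(N), rnorm(N)),
                        n = cbind(rnorm(N), rnorm(N)),
                        rank_names = c("iv1", "dv"))
  E <- effective_couplings(net, 1)$E
  expect_true(all(abs(E) < 4 / sqrt(N)))
})

test_that("pathway selection vector generalises across ranks", {
  # rank-1: n_tol is exactly n_dv
  net1 <- fix_rank1_net()
  g1 <- flow_graph(net1, 1)
  psv1 <- pathway_selection_vector(g1, net1)
  expect_identical(psv1$n_tol, psv1$components$order1)
  expect_equal(psv1$n_tol, net1$n[, "dv"], tolerance = 1e-12)

  # rank-3 family: n_tol aligns with the classical selection vector
  net <- fix_family_net()
  for (ctx in 1:2) {
    g <- flow_graph(net, ctx)
    psv <- pathway_selection_vector(g, net)
    lin <- linearize(net, lowrankCDM:::.ctx_embedding(net, ctx), context = ctx)
    cs <- sum(psv$n_tol * lin$s) / sqrt(sum(psv$n_tol^2) * sum(lin$s^2))
    expect_gt(cs, 0.99)
    # n_tol equals the sum of its order components
    expect_equal(psv$n_tol, Reduce(`+`, psv$components), tolerance = 1e-12)
  }

  # deeper chain: order components follow path-length grouping
  set.seed(42)
  N <- 500
  m <- matrix(rnorm(N * 3), N); n <- matrix(rnorm(N * 3), N)
  net3 <- network_params(rnorm(N), rnorm(N), numeric(N), numeric(N), rnorm(N),
                         m = m, n = n, rank_names = c("iv1", "iv2", "dv"))
  g3 <- graph_from_edges(
    c("inp1", "inp2", "iv1", "iv2", "dv"),
    data.frame(from = c("inp1", "iv1", "iv1", "iv2"),
               to = c("iv1", "iv2", "dv", "dv"),
               weight = c(0.5, 0.4, 0.3, 0.2)))
  psv3 <- pathway_selection_vector(g3, net3)
  expect_equal(psv3$components$order2,
               0.3 * n[, 1] + 0.2 * n[, 2], tolerance = 1e-12)
  expect_equal(psv3$components$order3, 0.4 * 0.2 * n[, 1], tolerance = 1e-12)
})

test_that("pathway and classical modulation decompositions agree", {
  net <- fix_family_net()
  pw <- pathway_modulation(net)
  cl <- classical_modulation(net, at = "ctx_embedding")
  th <- with(net$meta, beta * eta / (alpha + beta * eta))
  expect_close(pw$proportion_sv, th, 0.05)
  expect_close(pw$proportion_sv, cl$proportion_sv, 0.05)
  # components agree up to the ||m~_dv|| scale factor (definition equivalence)
  lin1 <- linearize(net, lowrankCDM:::.ctx_embedding(net, 1), context = 1)
  scale <- sqrt(sum((lin1$gain * net$m[, "dv"])^2))
  expect_close(cl$by_input$mod_inp[1] / scale, pw$by_input$mod_inp[1], 0.05)
  expect_close(cl$by_input$mod_sel[1] / scale, pw$by_input$mod_sel[1], 0.05)
})

test_that("identical context graphs yield a null modulation", {
  g <- graph_from_edges(c("inp1", "inp2", "iv1", "dv"),
                        data.frame(from = c("inp1", "iv1", "inp2"),
                                   to = c("iv1", "dv", "dv"),
                                   weight = c(0.5, 0.3, 0.2)))
  pm <- pathway_modulation(graphs = list(g, g))
  expect_equal(pm$mod_inp, 0)
  expect_equal(pm$mod_sel, 0)
  expect_true(is.na(pm$proportion_sv))
})

test_that("closed-form pulse response matches fine-step integration", {
  set.seed(43)
  # chains up to three intermediate variables with extra shortcut edges
  g <- graph_from_edges(
    c("inp1", "iv1", "iv2", "iv3", "dv"),
    data.frame(from = c("inp1", "inp1", "iv1", "iv2", "iv3", "iv1", "inp1"),
               to = c("iv1", "dv", "iv2", "iv3", "dv", "dv", "iv3"),
               weight = round(rnorm(7), 2)))
  tau <- g$tau
  tt <- seq(0, 12 * tau, by = tau / 100)
  cf <- pulse_response(g, c(inp1 = 0.9), tt)
  num <- integrate_flow_ode(g, c(inp1 = 0.9), dt = tau / 100,
                            n_steps = length(tt) - 1, method = "rk4")
  expect_lt(max(abs(cf - num)), 1e-6)
  # t = 0: nothing has reached the decision variable
  expect_equal(unname(cf[1, "dv"]), 0)
  # input variable decays as exp(-t/tau)
  expect_close(cf[, "inp1"], 0.9 * exp(-tt / tau), 1e-12)
  # long-time limit: total effective coupling
  late <- pulse_response(g, c(inp1 = 0.9), 60 * tau)
  expect_close(unname(late[1, "dv"]),
               0.9 * total_effective_coupling(g, "inp1"), 1e-6)
  expect_error(pulse_response(g, c(inp1 = 1), -5), ">= 0")
})

test_that("discrete information flow fills slots one hop per step", {
  # rank-1-style graph: content reaches dv at step 2 and is maintained
  gA <- graph_from_edges(c("inp1", "inp2", "dv"),
                         data.frame(from = c("inp1", "inp2"),
                                    to = c("dv", "dv"),
                                    weight = c(0.8, 0.01)))
  fl <- discrete_flow(gA, c(inp1 = 2, inp2 = 3), n_steps = 4)
  expect_equal(unname(fl[2, "dv"]), 0.8 * 2 + 0.01 * 3)
  expect_equal(unname(fl[3, "dv"]), unname(fl[2, "dv"]))
  expect_equal(unname(fl[2, "inp1"]), 0)
  # rank-3-style: dv first non-zero at step 3 via the intermediate hop
  gB <- graph_from_edges(c("inp1", "inp2", "iv1", "dv"),
                         data.frame(from = c("inp1", "iv1"),
                                    to = c("iv1", "dv"),
                                    weight = c(0.5, 0.6)))
  flB <- discrete_flow(gB, c(inp1 = 2), n_steps = 4)
  expect_equal(unname(flB[2, "dv"]), 0)
  expect_equal(unname(flB[2, "iv1"]), 1)
  expect_equal(unname(flB[3, "dv"]), 0.5 * 0.6 * 2)
  # zero pulses: nothing anywhere
  expect_true(all(discrete_flow(gB, c(inp1 = 0)) == 0))
})
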