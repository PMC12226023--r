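test_that("gaussian gain matches quadrature-independent oracles", {
  expect_equal(gaussian_gain("identity", 3.7), 1)
  expect_equal(gaussian_gain("tanh", 0), 1)
  # Monte-Carlo oracle
  set.seed(20)
  x <- rnorm(4e7)
  mc <- mean(1 - tanh(x)^2)
  expect_close(gaussian_gain("tanh", 1), mc, 1e-4)
  set.seed(20)
  mc_sp <- mean(1 / (1 + exp(-0.5 * rnorm(1e6))))
  expect_close(gaussian_gain("softplus", 0.5), mc_sp, 1e-3)
  expect_error(gaussian_gain("relu", 1), "unknown activation")
})

test_that("family construction realises the prescribed effective couplings", {
  # tolerances scale with the 1/sqrt(N/3) overlap-estimator noise
  net <- fix_family_net()      # alpha 0.5, beta 0.7, eta 0.4 at N = 6000
  tol <- 0.15                  # ~4 sd of the overlap estimator at this N
  e1 <- effective_couplings(net, 1)$E
  e2 <- effective_couplings(net, 2)$E
  expect_close(e1["inp1", "iv1"], 0.7, tol)
  expect_close(e1["inp1", "dv"], 0.5, tol)
  expect_close(e1["iv1", "dv"], 0.4, tol)
  expect_close(e1["dv", "dv"], 1, tol)
  expect_close(e2["dv", "dv"], 1, tol)
  # complementary couplings vanish in the other context
  expect_close(e2["inp1", "dv"], 0, tol)
  expect_close(e2["iv1", "dv"], 0, tol)
  expect_close(e2["inp2", "dv"], 0.5, tol)
  expect_close(e2["iv2", "dv"], 0.4, tol)
  # cross-couplings stay near zero
  expect_close(e1["inp1", "iv2"], 0, tol)
  expect_close(e1["iv1", "iv2"], 0, tol)
  expect_error(build_rank3_family(-0.1, 1, 1, N = 30), "non-negative")
  expect_error(build_rank3_family(1, 1, 1, N = 31), "divisible by 3")
})

test_that("mean-field recovery holds across random parameter draws", {
  set.seed(21)
  for (i in 1:5) {
    th <- runif(3)
    net <- build_rank3_family(th[1], th[2], th[3], N = 3000)
    e1 <- effective_couplings(net, 1)$E
    expect_close(c(e1["inp1", "iv1"], e1["inp1", "dv"], e1["iv1", "dv"]),
                 c(th[2], th[1], th[3]), 0.12)
  }
})

test_that("pure selection-vector network has no direct input-to-decision route", {
  net <- fix_pure_sv_net()
  g <- gaussian_gain("tanh", 1)
  for (ctx in 1:2) {
    E <- effective_couplings(net, ctx)$E
    expect_close(E["inp1", "dv"], 0, 0.1)
    expect_close(E["inp2", "dv"], 0, 0.1)
    expect_close(E["dv", "dv"], 1, 0.1)
  }
  # block zeros make the population-2/3 contribution of I1 to n_dv exactly 0
  Np <- net$N / 3
  expect_true(all(net$I1[(Np + 1):(3 * Np)] == 0))
  # relevant-context pathway couplings: beta = 10/3, eta = (1 - g^2)/3
  E1 <- effective_couplings(net, 1)$E
  expect_close(E1["inp1", "iv1"], 10 / 3, 0.5)
  expect_close(E1["iv1", "dv"], (1 - g^2) / 3, 0.1)
  # classical decomposition: pure selection-vector modulation
  cl <- classical_modulation(net, at = "ctx_embedding")
  expect_close(cl$proportion_sv, 1, 0.05)
})

test_that("family special case alpha = 0 reproduces the pure-SV coupling pattern", {
  set.seed(22)
  g <- gaussian_gain("tanh", 1)
  net <- build_rank3_family(0, 10 / 3, (1 - g^2) / 3, N = 3000)
  E1 <- effective_couplings(net, 1)$E
  ref <- effective_couplings(fix_pure_sv_net(), 1)$E
  for (edge in list(c("inp1", "iv1"), c("inp1", "dv"), c("iv1", "dv"),
                    c("dv", "dv"), c("inp2", "dv")))
    expect_close(E1[edge[1], edge[2]], ref[edge[1], edge[2]], 0.6)
})

test_that("counterexample pair: shared blocks identical, circuits distinct", {
  set.seed(23)
  pair <- build_counterexample_pair(N = 1500)
  cfg <- task_config()
  tb <- sample_trials(cfg, 2)
  s1 <- simulate_network(pair$rnn1, tb, record = "all")
  s2 <- simulate_network(pair$rnn2, tb, record = "all")
  Np <- 500
  # populations 1-2 never see the differing n_dv: traces agree exactly
  expect_lt(max(abs(s1$rates[1:(2 * Np), , ] - s2$rates[1:(2 * Np), , ])),
            1e-12)
  # connectivity matrices genuinely differ
  J1 <- full_connectivity(pair$rnn1); J2 <- full_connectivity(pair$rnn2)
  expect_gt(norm(J1 - J2, "F") / norm(J1, "F"), 0.1)
  # the pathway decomposition of the rerouted modality flips
  p1 <- pathway_modulation(pair$rnn1)$by_input
  p2 <- pathway_modulation(pair$rnn2)$by_input
  expect_gt(p2$proportion_sv[1] - p1$proportion_sv[1], 0.5)
})

test_that("redundant augmentation preserves computation and matches activity", {
  tm <- fix_trained_full()
  set.seed(24)
  red <- build_redundant(tm$net)
  expect_equal(red$N, 2 * tm$net$N)
  cfg <- task_config()
  set.seed(25)
  tb <- sample_trials(cfg, 20)
  z1 <- simulate_network(tm$net, tb)$z
  z2 <- simulate_network(red, tb)$z
  expect_lt(max(abs(z1 - z2)), 1e-8)
  expect_close(red$meta$activity_ratio, 1, 0.1)
  expect_error(build_redundant(fix_family_net()), "full-rank")
})
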