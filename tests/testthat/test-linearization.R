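test_that("slow point of a connection-free network is the context embedding", {
  set.seed(30)
  N <- 60
  net <- network_params(rnorm(N), rnorm(N), rnorm(N), rnorm(N), rnorm(N),
                        J = matrix(0, N, N))
  sp <- find_slow_point(net, 1)
  expect_close(sp$x, net$Ictx1, 1e-6)
  expect_lt(sp$residual, 1e-8)
})

test_that("slow points of handcrafted networks sit near the context embedding", {
  net <- fix_family_net()
  for (ctx in 1:2) {
    sp <- find_slow_point(net, ctx, tol = 1e-3)
    Ictx <- if (ctx == 1) net$Ictx1 else net$Ictx2
    expect_lt(sqrt(mean((sp$x - Ictx)^2)), 0.2)
  }
})

test_that("rank-1 linearisation: selection vector equals n_dv, s.rho = 1", {
  net <- fix_rank1_net(self_coupling = 1.0)
  lin <- linearize(net, numeric(net$N), context = 1)
  expect_close(lin$lambda_max, 0, 1e-10)
  cs <- sum(lin$s * net$n[, 1]) /
    sqrt(sum(lin$s^2) * sum(net$n[, 1]^2))
  expect_gt(abs(cs), 0.999999)
  expect_equal(sum(lin$s * lin$rho), 1, tolerance = 1e-10)
  # rank-1 theorem: M^T n_dv ~ 0 when <m~, n> ~ 1
  mt <- transition_apply(net, numeric(net$N), net$n[, 1], transpose = TRUE)
  expect_lt(sqrt(sum(mt^2) / sum(net$n[, 1]^2)), 0.05)
})

test_that("acceptance filter applies the closed eigenvalue interval", {
  # engineered rank-1 nets with exact leading eigenvalue <m, n> - 1
  accepted <- accept_network(fix_rank1_net(self_coupling = 1.02))
  expect_true(accepted$accepted)
  expect_close(accepted$eigenvalues, c(0.02, 0.02), 1e-6)
  rejected <- accept_network(fix_rank1_net(self_coupling = 1.1))
  expect_false(rejected$accepted)
  expect_match(rejected$reason, "outside")
  boundary <- accept_network(fix_rank1_net(self_coupling = 1.05))
  expect_true(boundary$accepted)   # closed interval convention
})

test_that("ambiguous or absent line attractors are reported", {
  # two eigenvalues in the band: duplicate the dv component
  net <- fix_rank1_net(self_coupling = 1.0)
  m2 <- cbind(net$m[, 1], c(net$m[-1, 1], net$m[1, 1]))
  n2 <- cbind(net$n[, 1], c(net$n[-1, 1], net$n[1, 1]))
  twin <- network_params(net$I1, net$I2, net$Ictx1, net$Ictx2, net$w,
                         m = m2, n = n2, rank_names = c("iv1", "dv"))
  expect_error(linearize(twin, numeric(net$N), context = 1), "ambiguous")
  # no eigenvalue anywhere near the band
  flat <- fix_rank1_net(self_coupling = 0.3)
  expect_error(linearize(flat, numeric(flat$N), context = 1),
               "line attractor")
})

test_that("classical decomposition is internally consistent", {
  net <- fix_family_net()
  ls <- lapply(1:2, function(ctx)
    linearize(net, lowrankCDM:::.ctx_embedding(net, ctx), context = ctx))
  cl <- classical_modulation(net, at = "ctx_embedding")
  # mod_inp + mod_sel equals the directly computed Delta(Itilde . s)
  direct1 <- sum(ls[[1]]$Itilde1 * ls[[1]]$s) - sum(ls[[2]]$Itilde1 * ls[[2]]$s)
  expect_equal(cl$by_input$mod_inp[1] + cl$by_input$mod_sel[1], direct1,
               tolerance = 1e-10)
  direct2 <- sum(ls[[2]]$Itilde2 * ls[[2]]$s) - sum(ls[[1]]$Itilde2 * ls[[1]]$s)
  expect_equal(cl$by_input$mod_inp[2] + cl$by_input$mod_sel[2], direct2,
               tolerance = 1e-10)
  # family nets: proportion matches beta*eta/(alpha + beta*eta)
  th <- with(net$meta, beta * eta / (alpha + beta * eta))
  expect_close(cl$proportion_sv, th, 0.05)
})

test_that("representation cosines separate the two mechanisms", {
  # pure-SV net: selection vector changes, input representation does not
  rc_sv <- representation_cosines(fix_pure_sv_net(), at = "ctx_embedding")
  expect_lt(rc_sv["selection_vector"], 0.9)
  expect_close(rc_sv["input1_representation"], 1, 1e-10)
  # identical context embeddings: everything has cosine 1
  net <- fix_rank1_net()
  ic <- 0.05 * net$I1          # small, so the gain stays near phi'(0) = 1
  same <- network_params(net$I1, net$I2, ic, ic, net$w,
                         m = net$m, n = net$n, rank_names = "dv")
  rc <- representation_cosines(same, at = "ctx_embedding")
  expect_close(unname(rc), c(1, 1, 1), 1e-10)
})
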