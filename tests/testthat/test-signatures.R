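test_that("effective dimension equals its singular-value definition", {
  set.seed(60)
  # rank-1 matrix
  u <- rnorm(20); v <- rnorm(15)
  expect_equal(effective_dimension(outer(u, v)), 1, tolerance = 1e-10)
  # k equal nonzero singular values
  for (k in c(2, 5)) {
    D <- diag(c(rep(3, k), rep(0, 12 - k)))
    expect_equal(effective_dimension(D), k, tolerance = 1e-12)
  }
  # random matrix vs an independent eigen-based computation
  J <- matrix(rnorm(30 * 30), 30)
  ev <- sort(eigen(crossprod(J), only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(effective_dimension(J), sum(ev) / ev[1], tolerance = 1e-10)
  # bounds property: 1 <= edim <= rank
  for (i in 1:10) {
    r <- sample(1:6, 1)
    A <- matrix(rnorm(12 * r), 12) %*% matrix(rnorm(r * 12), r)
    e <- effective_dimension(A)
    expect_gte(e, 1 - 1e-10)
    expect_lte(e, r + 1e-10)
  }
  expect_error(effective_dimension(matrix(0, 3, 3)), "zero matrix")
})

test_that("response-kernel regression recovers known kernels", {
  set.seed(61)
  cfg <- task_config()
  K <- 1000
  tb <- sample_trials(cfg, K)
  sti <- (cfg$n_fix + 1):(cfg$n_fix + cfg$n_sti)
  Tn <- cfg$n_sti
  tau_steps <- cfg$tau / cfg$dt
  # neuron 1: leaky trace of input 1 (same kernel in both contexts)
  kern_leak <- 0.8 * exp(-(0:(Tn - 1)) / tau_steps)
  # neuron 2: perfect integrator (step kernel)
  kern_step <- rep(0.5, Tn)
  conv <- function(u, k) {
    out <- numeric(length(u))
    for (t in seq_along(u)) out[t] <- sum(u[1:t] * rev(k[1:t]))
    out
  }
  choice <- sample(c(-1, 1), K, replace = TRUE)
  rates <- array(0, c(2, K, Tn))
  for (tr in 1:K) {
    u <- tb$u1[tr, sti]
    rates[1, tr, ] <- conv(u, kern_leak) + 0.2 * choice[tr] + 0.1
    rates[2, tr, ] <- conv(u, kern_step) - 0.1 * choice[tr]
  }
  fit <- fit_response_kernels(rates, tb, choice, ridge = 1e-4)
  expect_equal(fit$n_coef, 280L)
  for (ctx in 1:2) {
    rec <- fit$kernels[1, , 1, ctx]
    expect_lt(sqrt(sum((rec - kern_leak)^2) / sum(kern_leak^2)), 0.05)
    # integrator profile: flat, non-decaying
    rec2 <- fit$kernels[2, , 1, ctx]
    expect_lt(sqrt(sum((rec2 - kern_step)^2) / sum(kern_step^2)), 0.05)
    expect_gt(mean(rec2[31:40]) / mean(rec2[1:10]), 0.8)
    # no spillover into the input-2 kernels
    expect_lt(max(abs(fit$kernels[1, , 2, ctx])), 0.05)
  }
})

test_that("kernel modes normalise explained variance over the transient spectrum", {
  set.seed(62)
  # synthetic kernels spanned by two profiles
  Tn <- 40; N <- 30
  persistent <- rep(1, Tn)
  transient1 <- exp(-(0:(Tn - 1)) / 5)
  transient2 <- (0:(Tn - 1)) * exp(-(0:(Tn - 1)) / 5)
  kern <- array(0, c(N, Tn, 2, 2),
                dimnames = list(NULL, NULL, c("inp1", "inp2"),
                                c("ctx1", "ctx2")))
  for (i in 1:N) for (ctx in 1:2)
    kern[i, , 1, ctx] <- rnorm(1) * persistent + rnorm(1) * transient1 +
      0.3 * rnorm(1) * transient2
  fake <- structure(list(kernels = kern, ridge = 0, n_coef = 280L),
                    class = "response_kernels")
  md <- kernel_modes(fake, 1)
  expect_equal(sum(md$pev_transient), 1, tolerance = 1e-12)
  # SVD reconstruction oracle
  B <- cbind(t(kern[, , 1, 1]), t(kern[, , 1, 2]))
  sv <- svd(B)
  expect_lt(max(abs(B - sv$u %*% (sv$d * t(sv$v)))), 1e-10)
  expect_equal(md$singular_values, sv$d, tolerance = 1e-10)
  # three generating profiles: a third transient mode is absent
  expect_gt(pev_extra_modes(md), 0)
  expect_lt(sum(md$pev_transient[3:39]), 1e-6)
  # single dominant transient profile: extra-mode PEV ~ 0
  kern1 <- kern
  for (i in 1:N) for (ctx in 1:2)
    kern1[i, , 1, ctx] <- rnorm(1) * persistent + rnorm(1) * transient1
  md1 <- kernel_modes(structure(list(kernels = kern1), class = "response_kernels"), 1)
  expect_lt(pev_extra_modes(md1), 1e-6)
  # literal variant sums the whole transient spectrum
  expect_equal(pev_extra_modes(md, from_mode = 1), 1, tolerance = 1e-12)
  expect_error(kernel_modes(structure(list(kernels = kern * 0),
                                      class = "response_kernels"), 1),
               "all-zero")
})

test_that("TDR axes are orthonormal and trace the irrelevant input", {
  tm <- fix_trained_rank1()
  set.seed(63)
  cfg <- task_config()
  tb <- sample_trials(cfg, 600)
  sim <- simulate_network(tm$net, tb, record = "stimulus")
  ax <- tdr_axes(sim$rates, tb, sim$choice)
  G <- crossprod(ax$axes)
  expect_lt(max(abs(G - diag(4))), 1e-10)
  # irrelevant input still separates trajectories along its axis:
  # in context 2 (frequency relevant), input-1 strength still orders the
  # projections on the input-1 axis at mid-stimulus
  pr <- ax$projections
  pr2 <- pr[pr$context == 2 & pr$step == 20, ]
  agg <- tapply(pr2$on_input1, pr2$strength_loc, mean)
  strengths <- as.numeric(names(agg))
  expect_gt(cor(strengths, as.numeric(agg), method = "spearman"), 0.8)
})
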