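# Shared fixtures, built once per test run. Sizes are desk-scale: constructed
# networks use N = 3000 (tolerances widen as 1/sqrt(N/3) relative to the
# N = 30000 reference construction); trained fixtures are small and short.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_family_net <- function() fixture("family_net", function() {
  set.seed(101)
  build_rank3_family(alpha = 0.5, beta = 0.7, eta = 0.4, N = 6000)
})

fix_pure_sv_net <- function() fixture("pure_sv_net", function() {
  set.seed(102)
  build_rank3_pure_sv(N = 3000)
})

# a rank-1 network with an engineered line attractor: with zero context
# embeddings the slow point is x* = 0, the gain is 1, and the single
# nontrivial eigenvalue of M is <m, n> - 1
fix_rank1_net <- function(self_coupling = 1.0, N = 200, seed = 103) {
  set.seed(seed)
  m <- rnorm(N)
  n <- rnorm(N)
  n <- n - mean(n * m) / mean(m * m) * m     # orthogonalise
  n <- n + self_coupling / mean(m * m) * m   # set <m, n> exactly
  n <- n * 1                                  # keep scale
  stopifnot(abs(mean(m * n) - self_coupling) < 1e-12)
  network_params(I1 = rnorm(N), I2 = rnorm(N),
                 Ictx1 = numeric(N), Ictx2 = numeric(N),
                 w = m, m = cbind(m), n = cbind(n), rank_names = "dv")
}

# small trained networks (cached; used by several test files)
fix_trained_rank1 <- function() fixture("trained_rank1", function() {
  set.seed(104)
  train_network(train_config(N = 128, rank = 1, steps = 2500, batch = 128,
                             w_reg = 1e-4))
})

fix_trained_full <- function() fixture("trained_full", function() {
  set.seed(105)
  train_network(train_config(N = 64, rank = "full", steps = 800, batch = 64,
                             w_reg = 1e-3))
})

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("%s within %g of %s",
                              paste(signif(object, 4), collapse = ","), tol,
                              paste(signif(expected, 4), collapse = ",")))
}
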