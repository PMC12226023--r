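#' Gaussian-averaged gain of an activation function
#'
#' Computes `g(sigma) = integral N(0,1)(x) phi'(sigma x) dx`, the population
#' average of the single-neuron gain when pre-activations are centred Gaussian
#' with standard deviation `sigma`. This is the quantity the mean-field
#' constructions use: a population receiving a unit-variance context embedding
#' has average gain `g(1)` while ungated populations have gain `phi'(0)`.
#'
#' @param activation `"tanh"`, `"softplus"`, or `"identity"`.
#' @param sigma Standard deviation of the Gaussian pre-activation (>= 0).
#' @return The scalar gain.
#' @export
gaussian_gain <- function(activation = "tanh", sigma = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  dphi <- switch(activation,
                 tanh = function(x) 1 - tanh(x)^2,
                 softplus = function(x) 1 / (1 + exp(-x)),
                 identity = function(x) rep(1, length(x)),
                 stop("unknown activation '", activation, "'"))
  if (sigma == 0) return(dphi(0))
  stats::integrate(function(x) stats::dnorm(x) * dphi(sigma * x),
                   -Inf, Inf, rel.tol = 1e-12)$value
}

.gauss_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc), nr, nc)
.zeros <- function(n) numeric(n)

#' Handcraft a rank-3 network with pure selection-vector modulation
#'
#' Builds the three-population network in which the stimulus inputs reach the
#' decision variable only through intermediate variables: population 1 carries
#' the stimulus inputs, the decision-variable loop and the readout, while
#' populations 2 and 3 relay the intermediate variables and are gain-gated by
#' the context embeddings. Context changes the intermediate-to-decision
#' effective coupling (the selection vector) while leaving the input
#' representation untouched, so the contextual modulation is purely of the
#' selection-vector kind.
#'
#' All random structure comes from three standard-normal (N/3) x 3 matrices;
#' the block recipe fixes every connectivity vector in terms of their columns
#' and the Gaussian gain `g = gaussian_gain(activation, 1)` of the gated
#' population.
#'
#' @param N Total neuron count, divisible by 3 (default 30000).
#' @param activation Activation function name.
#' @return A low-rank `network_params` with components `iv1`, `iv2`, `dv`.
#' @export
build_rank3_pure_sv <- function(N = 30000, activation = "tanh") {
  if (N %% 3 != 0) stop("N must be divisible by 3")
  Np <- N / 3
  g <- gaussian_gain(activation, 1)
  M1 <- .gauss_mat(Np, 3); M2 <- .gauss_mat(Np, 3); M3 <- .gauss_mat(Np, 3)
  z <- .zeros(Np)
  I1    <- c(M1[, 1], z, z)
  I2    <- c(M1[, 2], z, z)
  Ictx1 <- c(z, M2[, 1], z)
  Ictx2 <- c(z, z, M3[, 1])
  m_iv1 <- c(z, M2[, 2], M3[, 2])
  m_iv2 <- c(z, M2[, 3], M3[, 3])
  m_dv  <- c(M1[, 3], z, z)
  n_iv1 <- c(10 * M1[, 1], z, z)
  n_iv2 <- c(10 * M1[, 2], z, z)
  n_dv  <- c(3 * M1[, 3], -g * M2[, 2] + M2[, 3], M3[, 2] - g * M3[, 3])
  w     <- c(4 * M1[, 3], z, z)
  network_params(I1, I2, Ictx1, Ictx2, w,
                 m = cbind(m_iv1, m_iv2, m_dv),
                 n = cbind(n_iv1, n_iv2, n_dv),
                 activation = activation,
                 rank_names = c("iv1", "iv2", "dv"),
                 meta = list(recipe = "rank3_pure_sv", N = N))
}

#' Handcraft a rank-3 network family with mixed modulation
#'
#' Mean-field construction of a three-population rank-3 network whose
#' effective couplings in the relevant context are, by design,
#' `E_inp->iv = beta` (input to intermediate variable), `E_inp->dv = alpha`
#' (direct input to decision variable) and `E_iv->dv = eta` (intermediate to
#' decision variable), with the complementary couplings vanishing in the
#' irrelevant context. The pathway decomposition of the contextual modulation
#' is then input modulation `alpha` and selection-vector modulation
#' `beta * eta`, so any modulation ratio can be dialled in.
#'
#' @param alpha,beta,eta Non-negative effective couplings of the
#'   input-to-decision, input-to-intermediate and intermediate-to-decision
#'   pathways.
#' @param N Total neuron count, divisible by 3.
#' @param activation Activation function name.
#' @return A low-rank `network_params` with components `iv1`, `iv2`, `dv`.
#' @export
build_rank3_family <- function(alpha, beta, eta, N = 30000,
                               activation = "tanh") {
  if (N %% 3 != 0) stop("N must be divisible by 3")
  if (alpha < 0 || beta < 0 || eta < 0)
    stop("alpha, beta and eta must be non-negative")
  Np <- N / 3
  g <- gaussian_gain(activation, 1)
  M1 <- .gauss_mat(Np, 3); M2 <- .gauss_mat(Np, 5); M3 <- .gauss_mat(Np, 5)
  z <- .zeros(Np)
  I1    <- c(M1[, 1], M2[, 1], M3[, 1])
  I2    <- c(M1[, 2], M2[, 2], M3[, 2])
  Ictx1 <- c(z, M2[, 3], z)
  Ictx2 <- c(z, z, M3[, 3])
  m_iv1 <- c(z, M2[, 4], M3[, 4])
  m_iv2 <- c(z, M2[, 5], M3[, 5])
  m_dv  <- c(M1[, 3], z, z)
  n_iv1 <- c(3 * beta * M1[, 1], z, z)
  n_iv2 <- c(3 * beta * M1[, 2], z, z)
  q <- 3 / (1 - g^2)
  n_dv <- c(3 * M1[, 3],
            -alpha * g * q * M2[, 1] + alpha * q * M2[, 2] -
              eta * g * q * M2[, 4] + eta * q * M2[, 5],
            alpha * q * M3[, 1] - alpha * g * q * M3[, 2] +
              eta * q * M3[, 4] - eta * g * q * M3[, 5])
  w <- c(4 * M1[, 3], z, z)
  network_params(I1, I2, Ictx1, Ictx2, w,
                 m = cbind(m_iv1, m_iv2, m_dv),
                 n = cbind(n_iv1, n_iv2, n_dv),
                 activation = activation,
                 rank_names = c("iv1", "iv2", "dv"),
                 meta = list(recipe = "rank3_family", N = N,
                             alpha = alpha, beta = beta, eta = eta))
}

#' Construct a pair of networks with identical activity but different circuits
#'
#' Builds two rank-3 networks that share every connectivity vector except the
#' decision variable's input-selection vector `n_dv`. The two choices of
#' `n_dv` route the stimulus information through different pathways (one
#' dominated by input modulation, the other by selection-vector modulation),
#' yet the resulting single-neuron activity traces are identical for any
#' shared input because the latent dynamics they induce coincide.
#'
#' @param N Total neuron count, divisible by 3 (default 30000).
#' @param activation Activation function name.
#' @return A list with elements `rnn1` and `rnn2`.
#' @export
build_counterexample_pair <- function(N = 30000, activation = "tanh") {
  if (N %% 3 != 0) stop("N must be divisible by 3")
  Np <- N / 3
  g <- gaussian_gain(activation, 1)
  M1 <- .gauss_mat(Np, 5); M2 <- .gauss_mat(Np, 5); M3 <- .gauss_mat(Np, 1)
  z <- .zeros(Np)
  I1    <- c(M1[, 1], M2[, 1], z)
  I2    <- c(M1[, 2], M2[, 2], z)
  Ictx1 <- c(M1[, 5], z, z)
  Ictx2 <- c(z, M2[, 5], z)
  m_iv1 <- c(M1[, 3], M2[, 3], z)
  m_iv2 <- c(M1[, 4], M2[, 4], z)
  m_dv  <- c(z, z, M3[, 1])
  n_iv1 <- c(3 / (1 + g) * M1[, 1], 3 / (1 + g) * M2[, 1], z)
  n_iv2 <- c(-3 * g / (1 - g^2) * M1[, 1], 3 / (1 - g^2) * M2[, 1], z)
  n_dv1 <- c(3 / (1 + g) * M1[, 4], 3 / (1 + g) * M2[, 4], z) +
    c(3 / (1 - g^2) * M1[, 2], -3 * g / (1 - g^2) * M2[, 2], z) +
    c(z, z, 3 * M3[, 1])
  n_dv2 <- c(-3 * g / (1 - g^2) * M1[, 3], 3 / (1 - g^2) * M2[, 3], z) +
    c(3 / (1 - g^2) * M1[, 2], -3 * g / (1 - g^2) * M2[, 2], z) +
    c(z, z, 3 * M3[, 1])
  w <- c(z, z, 4 * M3[, 1])
  make <- function(n_dv, tag) {
    network_params(I1, I2, Ictx1, Ictx2, w,
                   m = cbind(m_iv1, m_iv2, m_dv),
                   n = cbind(n_iv1, n_iv2, n_dv),
                   activation = activation,
                   rank_names = c("iv1", "iv2", "dv"),
                   meta = list(recipe = paste0("counterexample_", tag), N = N))
  }
  list(rnn1 = make(n_dv1, "rnn1"), rnn2 = make(n_dv2, "rnn2"))
}

#' Augment a full-rank network with a task-irrelevant population
#'
#' Builds a 2N-neuron network whose first population is an exact copy of
#' `net` and whose second population receives input through random embeddings
#' (entrywise standard deviation matched to the originals), has zero readout,
#' and is recurrently connected only within itself. The within-population
#' random weights of the second population are calibrated by simulation so
#' that the two populations have (nearly) equal average sum-of-squares
#' activity. Because the two blocks are disconnected and the readout ignores
#' the second one, the augmented network computes exactly as the original
#' while carrying substantial task-irrelevant activity variance.
#'
#' @param net A full-rank `network_params`.
#' @param config Task configuration used for the activity calibration.
#' @param n_calib Trials used per calibration simulation.
#' @param tol_ratio Accepted relative mismatch of the two populations'
#'   average sum-of-squares activity (default 0.1).
#' @return A full-rank `network_params` with 2N neurons.
#' @export
build_redundant <- function(net, config = task_config(), n_calib = 64,
                            tol_ratio = 0.1) {
  stopifnot(inherits(net, "network_params"))
  if (net$lowrank) stop("build_redundant supports full-rank networks only")
  N <- net$N
  emb_sd <- function(v) stats::sd(v)
  I1b <- stats::rnorm(N, 0, emb_sd(net$I1))
  I2b <- stats::rnorm(N, 0, emb_sd(net$I2))
  Ic1b <- stats::rnorm(N, 0, emb_sd(net$Ictx1))
  Ic2b <- stats::rnorm(N, 0, emb_sd(net$Ictx2))
  J2_unit <- .gauss_mat(N, N)
  batch <- sample_trials(config, n_calib)
  pop_mss <- function(scale) {
    J2 <- scale * J2_unit
    # readout is mean(w * phi): doubling the population would halve z, so the
    # first population's readout weights are doubled to preserve the output
    big <- network_params(c(net$I1, I1b), c(net$I2, I2b),
                          c(net$Ictx1, Ic1b), c(net$Ictx2, Ic2b),
                          c(2 * net$w, .zeros(N)),
                          J = rbind(cbind(net$J, matrix(0, N, N)),
                                    cbind(matrix(0, N, N), J2)),
                          activation = net$activation, tau = net$tau,
                          meta = list(recipe = "redundant", scale = scale))
    sim <- simulate_network(big, batch, record = "all")
    r2 <- apply(sim$rates^2, 1, mean)  # per-neuron mean square rate
    list(net = big, ratio = sum(r2[(N + 1):(2 * N)]) / sum(r2[1:N]))
  }
  # bisection on the log-scale of the within-population weight std
  scale <- stats::sd(net$J)
  res <- pop_mss(scale)
  for (i in 1:12) {
    if (abs(res$ratio - 1) <= tol_ratio) break
    scale <- scale * (1 / res$ratio)^0.35
    res <- pop_mss(scale)
  }
  if (abs(res$ratio - 1) > tol_ratio)
    warning(sprintf("population activity ratio %.3f outside +/-%g band",
                    res$ratio, tol_ratio))
  res$net$meta$activity_ratio <- res$ratio
  res$net
}
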