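# Task-irrelevant subspace search by orthogonality-constrained optimisation.
#
# The lesioned network has connectivity J' = J (E - Q Q^T): all recurrent
# input arriving through the subspace spanned by the orthonormal columns of
# Q is removed. Q is parameterised through the Cayley transform of a free
# matrix A, C = (E + S)(E - S)^{-1} with S = A - A^T, taking the first r
# columns, which keeps Q exactly orthonormal throughout the optimisation.

# pulse protocol: context 1 on, unit pulse on input 1 at the first step,
# 40 steps of the task's Euler grid
.pulse_protocol <- function(net, n_steps = 40, dt = 20) {
  a <- dt / net$tau
  act <- .act_fun(net$activation)
  list(a = a, act = act, n_steps = n_steps,
       x0 = net$Ictx1, u1 = c(1, numeric(n_steps - 1)))
}

.pulse_sim <- function(net, J, proto) {
  x <- proto$x0
  F_hat <- matrix(0, proto$n_steps, net$N)
  Xs <- matrix(0, net$N, proto$n_steps + 1)
  Xs[, 1] <- x
  for (t in seq_len(proto$n_steps)) {
    ph <- proto$act$phi(x)
    x <- (1 - proto$a) * x +
      proto$a * (drop(J %*% ph) + net$I1 * proto$u1[t] + net$Ictx1)
    Xs[, t + 1] <- x
    F_hat[t, ] <- proto$act$phi(x)
  }
  list(states = Xs, rates = F_hat,
       z_final = mean(net$w * proto$act$phi(x)))
}

#' Find a task-irrelevant activity subspace
#'
#' Gradient optimisation (Adam) of the lesion loss
#' `lambda (z_T - z_T_hat)^2 / z_T_hat^2 + (1 - ||f_hat Q||^2 / ||f_hat||^2)`
#' over the Cayley-parameterised orthonormal basis `Q` of an r-dimensional
#' subspace. `f_hat` is the pulse-driven activity (40 steps x N) of the
#' unlesioned network under the unit-pulse protocol (input 1, context 1) and
#' `z_T`, `z_T_hat` are the final outputs with and without the lesion
#' `J' = J (E - Q Q^T)`. The first term preserves behaviour, the second
#' maximises the activity variance captured by the lesioned subspace.
#'
#' @param net A full-rank `network_params`.
#' @param r Subspace dimension (default 10).
#' @param lambda Weight of the output-preservation term (default 10).
#' @param lr Adam learning rate (default 1e-5).
#' @param steps Optimisation steps (default 2000).
#' @param init_scale Scale of the random initialisation of `A`.
#' @return A `lesion_result`: `Q` (N x r orthonormal), `trace` data frame
#'   (step, captured, deviation, loss), final `captured` and `deviation`.
#' @export
irrelevant_subspace <- function(net, r = 10, lambda = 10, lr = 1e-5,
                                steps = 2000, init_scale = 1e-3) {
  stopifnot(inherits(net, "network_params"))
  if (net$lowrank) stop("lesion analysis applies to full-rank networks")
  N <- net$N
  if (r >= N) stop("r must be smaller than N")
  proto <- .pulse_protocol(net)
  ref <- .pulse_sim(net, net$J, proto)
  f_hat <- ref$rates
  fss <- sum(f_hat^2)
  z_hat <- ref$z_final
  ftf <- crossprod(f_hat)                      # N x N
  A <- matrix(stats::rnorm(N * N, 0, init_scale), N, N)
  m1 <- matrix(0, N, N); m2 <- matrix(0, N, N)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  I_N <- diag(N)
  trace <- data.frame(step = seq_len(steps), captured = NA_real_,
                      deviation = NA_real_, loss = NA_real_)
  Q <- NULL
  for (it in seq_len(steps)) {
    S <- A - t(A)
    W <- solve(I_N - S)
    C <- (I_N + S) %*% W
    Q <- C[, seq_len(r), drop = FALSE]
    Jp <- net$J - (net$J %*% Q) %*% t(Q)
    sim <- .pulse_sim(net, Jp, proto)
    dev <- (sim$z_final - z_hat)^2 / z_hat^2
    captured <- sum((f_hat %*% Q)^2) / fss
    trace$captured[it] <- captured
    trace$deviation[it] <- dev
    trace$loss[it] <- lambda * dev + (1 - captured)
    # gradient of the output term through the 40-step simulation (BPTT)
    dz <- 2 * lambda * (sim$z_final - z_hat) / z_hat^2
    xT <- sim$states[, proto$n_steps + 1]
    g <- proto$act$dphi(xT) * net$w * dz / N
    gJ <- matrix(0, N, N)
    for (t in proto$n_steps:1) {
      ph_prev <- proto$act$phi(sim$states[, t])
      gJ <- gJ + proto$a * tcrossprod(g, ph_prev)
      g <- (1 - proto$a) * g +
        proto$a * proto$act$dphi(sim$states[, t]) * drop(crossprod(Jp, g))
    }
    dQ <- -(crossprod(net$J, gJ) + crossprod(gJ, net$J)) %*% Q
    dQ <- dQ - 2 * (ftf %*% Q) / fss
    Gbar <- matrix(0, N, N)
    Gbar[, seq_len(r)] <- dQ
    dS <- crossprod(I_N + C, Gbar) %*% t(W)
    dA <- dS - t(dS)
    m1 <- b1 * m1 + (1 - b1) * dA
    m2 <- b2 * m2 + (1 - b2) * dA^2
    A <- A - lr * (m1 / (1 - b1^it)) / (sqrt(m2 / (1 - b2^it)) + eps)
  }
  if (max(abs(crossprod(Q) - diag(r))) > 1e-8)
    stop("internal error: Cayley-parameterised Q lost orthonormality")
  structure(list(Q = Q, trace = trace,
                 captured = trace$captured[steps],
                 deviation = trace$deviation[steps]),
            class = "lesion_result")
}

#' Explained variance of task-irrelevant activity
#'
#' The maximum captured-variance ratio attained along the optimisation trace
#' among iterates whose relative output deviation satisfies the feasibility
#' constraint (default `< 1e-3`). Returns 0 (with attribute
#' `feasible = FALSE`) when no iterate is feasible.
#'
#' @param result A `lesion_result`, or its `trace` data frame.
#' @param dev_tol Output-deviation constraint.
#' @export
pev_irrelevant_activity <- function(result, dev_tol = 1e-3) {
  trace <- if (inherits(result, "lesion_result")) result$trace else result
  ok <- trace$deviation < dev_tol
  if (!any(ok)) return(structure(0, feasible = FALSE))
  structure(max(trace$captured[ok]), feasible = TRUE)
}

#' Cayley transform of a square matrix
#'
#' `C = (E + S)(E - S)^{-1}` with `S = A - A^T`; orthogonal for any `A`.
#' @param A Square matrix.
#' @export
cayley_orthogonal <- function(A) {
  S <- A - t(A)
  I_N <- diag(nrow(A))
  (I_N + S) %*% solve(I_N - S)
}
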