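#' Simulate a network on a batch of trials
#'
#' Integrates the rate equation
#' `tau dx/dt = -x + J phi(x) + I1 u1 + I2 u2 + Ictx1 uctx1 + Ictx2 uctx2 + eps`
#' with Euler steps of size `dt` (the task's time bin), starting each trial at
#' `x(0) = Ictx` of the trial's context. Output is the linear readout
#' `z(t) = mean(w * phi(x(t)))`; the choice is the sign of the mean output over
#' the decision period.
#'
#' @param net A [network_params()] object.
#' @param batch A `cdm_trials` batch from [sample_trials()].
#' @param noise_std Standard deviation of per-step white process noise
#'   (default 0).
#' @param record Which steps' rates to keep: `"none"` (default), `"stimulus"`,
#'   or `"all"`. Rates are `phi(x)`, returned as an N x trials x steps array.
#' @return A list of class `sim_result`: `z` (trials x steps), `choice`
#'   (+1/-1 per trial), and optionally `rates` with `recorded_steps`.
#' @export
simulate_network <- function(net, batch, noise_std = 0,
                             record = c("none", "stimulus", "all")) {
  stopifnot(inherits(net, "network_params"), inherits(batch, "cdm_trials"))
  record <- match.arg(record)
  if (noise_std < 0) stop("noise_std must be >= 0")
  cfg <- batch$config
  if (abs(cfg$tau - net$tau) > 1e-9)
    stop("batch time constant does not match the network's tau")
  n_steps <- ncol(batch$u1)
  rec_steps <- switch(record,
                      none = integer(0),
                      stimulus = seq(cfg$n_fix + 1L, cfg$n_fix + cfg$n_sti),
                      all = seq_len(n_steps))
  X0 <- matrix(0, net$N, nrow(batch$u1))
  ctx <- batch$meta$context
  X0[, ctx == 1] <- net$Ictx1
  X0[, ctx == 2] <- net$Ictx2
  In <- cbind(net$I1, net$I2, net$Ictx1, net$Ictx2)
  res <- .simulate_cpp(In, net$w,
                       if (net$lowrank) matrix(0, 0, 0) else net$J,
                       if (net$lowrank) net$m else matrix(0, 0, 0),
                       if (net$lowrank) net$n else matrix(0, 0, 0),
                       net$lowrank, net$activation, cfg$dt, net$tau,
                       noise_std, batch$u1, batch$u2, batch$u_ctx1,
                       batch$u_ctx2, X0, as.integer(rec_steps))
  zdec <- rowMeans(res$z[, batch$decision_mask, drop = FALSE])
  if (any(zdec == 0))
    warning("tied decision output (z = 0) broken towards +1")
  choice <- ifelse(zdec >= 0, 1, -1)
  out <- list(z = res$z, choice = choice, decision_output = zdec)
  if (length(rec_steps) > 0) {
    out$rates <- res$rates
    out$recorded_steps <- rec_steps
  }
  structure(out, class = "sim_result")
}

#' Simulate the latent task-variable dynamics of a low-rank network
#'
#' For a low-rank network started at `x(0) = Ictx`, the state stays in the
#' span of the context embedding, the output vectors `m_r`, and the stimulus
#' embeddings, so the N-dimensional dynamics reduce to an (R + 2)-dimensional
#' system: input variables obey `tau dk_s/dt = -k_s + u_s(t)` and each
#' internal variable obeys
#' `tau dk_r/dt = -k_r + <n_r, phi(Ictx + sum_j k_j m_j + sum_s k_s I_s)>`.
#'
#' When `batch` is a `cdm_trials` object the latent system is integrated on
#' the task's Euler grid, so the reconstruction
#' `x(t) = Ictx + sum_r k_r m_r + sum_s k_s I_s` reproduces the full
#' simulation exactly. A plain list `list(u1 =, u2 =, context =, dt =)` with
#' trials-by-steps input matrices can be supplied instead for fine-step
#' integration; `method = "rk4"` then provides a high-accuracy oracle mode.
#'
#' @param net A low-rank [network_params()] object.
#' @param batch A `cdm_trials` batch or a list as described above.
#' @param method `"euler"` (the model's own discretisation) or `"rk4"`.
#' @return A list of class `latent_trajectory`: `k_inp1`, `k_inp2`
#'   (trials x steps), `k` (trials x steps x R), `context`, and `dt`.
#' @export
simulate_latent <- function(net, batch, method = c("euler", "rk4")) {
  stopifnot(inherits(net, "network_params"))
  if (!net$lowrank) stop("latent simulation requires a low-rank network")
  method <- match.arg(method)
  if (inherits(batch, "cdm_trials")) {
    u1 <- batch$u1; u2 <- batch$u2
    context <- batch$meta$context
    dt <- batch$config$dt
  } else {
    u1 <- as.matrix(batch$u1); u2 <- as.matrix(batch$u2)
    context <- batch$context
    dt <- batch$dt
  }
  ntr <- nrow(u1); n_steps <- ncol(u1); R <- ncol(net$m)
  act <- .act_fun(net$activation)
  a <- dt / net$tau
  k_inp1 <- matrix(0, ntr, n_steps)
  k_inp2 <- matrix(0, ntr, n_steps)
  karr <- array(0, c(ntr, n_steps, R), dimnames = list(NULL, NULL, colnames(net$m)))
  for (tr in seq_len(ntr)) {
    Ictx <- .ctx_embedding(net, context[tr])
    kp <- c(0, 0); kr <- numeric(R)
    deriv <- function(kp, kr, u) {
      x <- Ictx + drop(net$m %*% kr) + kp[1] * net$I1 + kp[2] * net$I2
      ph <- act$phi(x)
      list(dkp = (-kp + u) / net$tau,
           dkr = (-kr + drop(crossprod(net$n, ph)) / net$N) / net$tau)
    }
    for (t in seq_len(n_steps)) {
      u <- c(u1[tr, t], u2[tr, t])
      if (method == "euler") {
        d <- deriv(kp, kr, u)
        kp <- kp + dt * d$dkp
        kr <- kr + dt * d$dkr
      } else {
        d1 <- deriv(kp, kr, u)
        d2 <- deriv(kp + dt / 2 * d1$dkp, kr + dt / 2 * d1$dkr, u)
        d3 <- deriv(kp + dt / 2 * d2$dkp, kr + dt / 2 * d2$dkr, u)
        d4 <- deriv(kp + dt * d3$dkp, kr + dt * d3$dkr, u)
        kp <- kp + dt / 6 * (d1$dkp + 2 * d2$dkp + 2 * d3$dkp + d4$dkp)
        kr <- kr + dt / 6 * (d1$dkr + 2 * d2$dkr + 2 * d3$dkr + d4$dkr)
      }
      k_inp1[tr, t] <- kp[1]; k_inp2[tr, t] <- kp[2]
      karr[tr, t, ] <- kr
    }
  }
  structure(list(k_inp1 = k_inp1, k_inp2 = k_inp2, k = karr,
                 context = context, dt = dt),
            class = "latent_trajectory")
}

#' Reconstruct the full state from a latent trajectory
#' @param net The low-rank network used for [simulate_latent()].
#' @param latent A `latent_trajectory`.
#' @param trial Trial index.
#' @return N x steps matrix of reconstructed states `x(t)`.
#' @export
latent_reconstruct <- function(net, latent, trial = 1) {
  stopifnot(inherits(latent, "latent_trajectory"))
  Ictx <- .ctx_embedding(net, latent$context[trial])
  n_steps <- ncol(latent$k_inp1)
  R <- dim(latent$k)[3]
  K <- t(matrix(latent$k[trial, , ], ncol = R))
  X <- net$m %*% K +
    outer(net$I1, latent$k_inp1[trial, ]) +
    outer(net$I2, latent$k_inp2[trial, ])
  X + Ictx
}

# generate trials with forced per-trial probabilities / context (R fallback
# used by psychometric_curve; statistics identical to sample_trials)
.forced_trials <- function(config, p_loc, p_frq, context) {
  ntr <- length(p_loc)
  n_steps <- config$n_fix + config$n_sti + config$n_dec
  u1 <- matrix(0, ntr, n_steps); u2 <- matrix(0, ntr, n_steps)
  sti <- seq(config$n_fix + 1L, config$n_fix + config$n_sti)
  for (tr in seq_len(ntr)) {
    np <- stats::rpois(config$n_sti, config$pulse_rate)
    nr <- stats::rbinom(config$n_sti, np, p_loc[tr])
    nh <- stats::rbinom(config$n_sti, np, p_frq[tr])
    u1[tr, sti] <- config$input_gain * (2 * nr - np)
    u2[tr, sti] <- config$input_gain * (2 * nh - np)
  }
  uc1 <- matrix(as.numeric(context == 1), ntr, n_steps)
  uc2 <- matrix(as.numeric(context == 2), ntr, n_steps)
  mask <- rep(FALSE, n_steps)
  mask[(n_steps - config$n_dec + 1L):n_steps] <- TRUE
  target <- ifelse(context == 1, sign(2 * p_loc - 1), sign(2 * p_frq - 1))
  meta <- data.frame(context = context,
                     context_label = ifelse(context == 1, "LOC", "FRQ"),
                     p_loc = p_loc, p_frq = p_frq,
                     strength_loc = 2 * p_loc - 1,
                     strength_frq = 2 * p_frq - 1)
  structure(list(u1 = u1, u2 = u2, u_ctx1 = uc1, u_ctx2 = uc2,
                 target = target, decision_mask = mask, meta = meta,
                 config = config),
            class = "cdm_trials")
}

#' Psychometric curves of a network
#'
#' For each context and each input modality, fixes that modality's per-trial
#' probability at each admissible value (the other modality's probability is
#' drawn at random) and reports the fraction of rightward (+1) choices with a
#' binomial standard error.
#'
#' @param net A `network_params` object.
#' @param config A [task_config()].
#' @param n_per_condition Trials per (context, input, strength) cell.
#' @param noise_std Process noise passed to [simulate_network()].
#' @return Data frame with columns context, input, strength, p_right, se, n.
#' @export
psychometric_curve <- function(net, config, n_per_condition = 50,
                               noise_std = 0) {
  rows <- list()
  for (ctx in 1:2) for (inp in 1:2) for (p in sort(config$strength_probs)) {
    rand_p <- sample(config$strength_probs, n_per_condition, replace = TRUE)
    p_loc <- if (inp == 1) rep(p, n_per_condition) else rand_p
    p_frq <- if (inp == 2) rep(p, n_per_condition) else rand_p
    tb <- .forced_trials(config, p_loc, p_frq, rep(ctx, n_per_condition))
    sim <- simulate_network(net, tb, noise_std = noise_std)
    pr <- mean(sim$choice == 1)
    rows[[length(rows) + 1L]] <- data.frame(
      context = ctx, input = inp, strength = 2 * p - 1, p_right = pr,
      se = sqrt(pr * (1 - pr) / n_per_condition), n = n_per_condition)
  }
  do.call(rbind, rows)
}
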