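#' Training configuration
#'
#' Hyperparameters for gradient training of networks on the pulse-based CDM
#' task: Adam (moment decays 0.9 / 0.99), squared output error at the decision
#' step plus an L2 penalty on the recurrent parameters (`sum J_ij^2` for
#' full-rank networks, `sum_r ||m_r||^2 + ||n_r||^2` for low-rank ones).
#'
#' @param N Neuron count.
#' @param rank Rank constraint (integer) or `"full"`.
#' @param activation Activation function name.
#' @param lr Learning rate.
#' @param steps Number of gradient steps.
#' @param batch Trials per gradient step.
#' @param w_reg Regularisation weight.
#' @param init Parameter initialisation: `"1/N2"` (Gaussian, variance 1/N^2,
#'   default) or `"1/N"` (variance 1/N).
#' @param noise_std Process-noise std during training (default 0).
#' @return A `train_config` list.
#' @export
train_config <- function(N = 512, rank = 1, activation = "tanh", lr = 1e-3,
                         steps = 5000, batch = 256, w_reg = 1e-4,
                         init = c("1/N2", "1/N"), noise_std = 0) {
  init <- match.arg(init)
  if (steps <= 0) stop("steps must be positive")
  if (w_reg < 0) stop("w_reg must be >= 0")
  structure(list(N = N, rank = rank, activation = activation, lr = lr,
                 beta1 = 0.9, beta2 = 0.99, steps = steps, batch = batch,
                 w_reg = w_reg, init = init, noise_std = noise_std),
            class = "train_config")
}

#' Masked squared-error training loss
#'
#' Reference implementation of the loss the trainer minimises: squared output
#' error summed over trials and masked steps, plus the L2 penalty on the
#' recurrent parameters of `net`.
#'
#' @param outputs Trials x steps matrix of network outputs.
#' @param targets Per-trial target (+1/-1).
#' @param mask Logical per-step decision mask (must select at least one step).
#' @param net A `network_params` (for the penalty term); may be `NULL` with
#'   `w_reg = 0`.
#' @param w_reg Regularisation weight.
#' @export
training_loss <- function(outputs, targets, mask, net = NULL, w_reg = 0) {
  if (!any(mask)) stop("decision mask selects no step")
  if (nrow(outputs) != length(targets) || ncol(outputs) != length(mask))
    stop("shape mismatch between outputs, targets and mask")
  err <- sum((outputs[, mask, drop = FALSE] - targets)^2)
  if (w_reg > 0 && !is.null(net)) {
    err <- err + if (net$lowrank)
      w_reg * (sum(net$m^2) + sum(net$n^2)) else w_reg * sum(net$J^2)
  }
  err
}

#' Train a network by backpropagation through time
#'
#' Trains all input embeddings, the recurrent parameters (low-rank vectors or
#' the full matrix), and the readout, sampling a fresh trial batch per step.
#' Randomness (initialisation and trial sampling) comes from R's global RNG.
#'
#' @param config A [train_config()].
#' @param task A [task_config()].
#' @return A `trained_model` list: `net` (`network_params`), `loss_trace`,
#'   `accepted` flag and `eigenvalues` from [accept_network()], and `config`.
#' @export
train_network <- function(config, task = task_config()) {
  stopifnot(inherits(config, "train_config"))
  lowrank <- !identical(config$rank, "full")
  R <- if (lowrank) as.integer(config$rank) else 0L
  init_sd <- if (config$init == "1/N2") 1 / config$N else 1 / sqrt(config$N)
  res <- .train_cpp(as.integer(config$N), R, lowrank,
                    task$n_fix, task$n_sti, task$n_dec,
                    task$pulse_rate, task$input_gain, task$strength_probs,
                    as.integer(config$steps), as.integer(config$batch),
                    config$lr, config$beta1, config$beta2, config$w_reg,
                    init_sd, config$noise_std, config$activation)
  net <- if (lowrank)
    network_params(res$In[, 1], res$In[, 2], res$In[, 3], res$In[, 4], res$w,
                   m = res$m, n = res$n, activation = config$activation,
                   tau = task$tau, meta = list(recipe = "trained_lowrank"))
  else
    network_params(res$In[, 1], res$In[, 2], res$In[, 3], res$In[, 4], res$w,
                   J = res$J, activation = config$activation, tau = task$tau,
                   meta = list(recipe = "trained_fullrank"))
  acc <- accept_network(net)
  structure(list(net = net, loss_trace = res$loss_trace,
                 accepted = acc$accepted, eigenvalues = acc$eigenvalues,
                 reason = acc$reason, config = config),
            class = "trained_model")
}

#' Line-attractor acceptance filter
#'
#' A network is accepted when the linearised dynamics around the slow point
#' form an approximate line attractor in both contexts: the largest real part
#' among the eigenvalues of the activity transition matrix must fall within
#' the closed interval [-0.05, 0.05] in each context.
#'
#' @param net A `network_params`.
#' @param band Half-width of the acceptance interval (default 0.05).
#' @return List with `accepted` flag, the per-context leading `eigenvalues`,
#'   and a `reason` string when rejected.
#' @export
accept_network <- function(net, band = 0.05) {
  ev <- c(NA_real_, NA_real_)
  for (ctx in 1:2) {
    sp <- tryCatch(find_slow_point(net, ctx), error = function(e) e)
    if (inherits(sp, "error"))
      return(list(accepted = FALSE, eigenvalues = ev,
                  reason = paste0("slow-point search failed in context ", ctx,
                                  ": ", conditionMessage(sp))))
    ev[ctx] <- .leading_eigenvalue(net, sp$x)
  }
  # closed interval; tiny grace so boundary eigenvalues survive rounding
  ok <- all(is.finite(ev)) && all(ev >= -band - 1e-10 & ev <= band + 1e-10)
  list(accepted = ok, eigenvalues = ev,
       reason = if (ok) NA_character_ else
         sprintf("leading eigenvalues (%.4f, %.4f) outside [-%g, %g]",
                 ev[1], ev[2], band, band))
}

#' Train an ensemble over a regularisation grid
#'
#' Trains `n_per_value` networks for every regularisation weight in `grid`,
#' applies the line-attractor acceptance filter, and returns all models with
#' their provenance.
#'
#' @param grid Vector of regularisation weights.
#' @param n_per_value Networks per grid value.
#' @param config Base [train_config()]; its `w_reg` is overridden.
#' @param task A [task_config()].
#' @param progress Print one line per trained network.
#' @return List with `models` (all `trained_model`s) and `manifest`
#'   (data frame: w_reg, replicate, accepted, leading eigenvalues, final loss).
#' @export
train_ensemble <- function(grid, n_per_value, config = train_config(),
                           task = task_config(), progress = FALSE) {
  if (length(grid) == 0)
    return(list(models = list(),
                manifest = data.frame(w_reg = numeric(0),
                                      replicate = integer(0),
                                      accepted = logical(0))))
  models <- list()
  rows <- list()
  for (wr in grid) {
    for (i in seq_len(n_per_value)) {
      cfg <- config
      cfg$w_reg <- wr
      tm <- train_network(cfg, task)
      models[[length(models) + 1L]] <- tm
      rows[[length(rows) + 1L]] <- data.frame(
        w_reg = wr, replicate = i, accepted = tm$accepted,
        ev_ctx1 = tm$eigenvalues[1], ev_ctx2 = tm$eigenvalues[2],
        final_loss = utils::tail(tm$loss_trace, 1))
      if (progress)
        message(sprintf("w_reg=%g rep=%d accepted=%s", wr, i, tm$accepted))
    }
  }
  list(models = models, manifest = do.call(rbind, rows))
}

#' The regularisation grid used for the full-rank network sweep
#' @return The 20-value grid `{0, 0.001, ..., 0.009, 0.01, 0.02, ..., 0.1}`.
#' @export
default_reg_grid <- function() {
  c(0, seq(0.001, 0.009, by = 0.001), seq(0.01, 0.1, by = 0.01))
}
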