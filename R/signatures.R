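#' Effective dimension (stable rank) of a matrix
#'
#' `edim(J) = sum_i sigma_i^2 / sigma_1^2` over the singular values of `J`.
#' Equals the rank when all nonzero singular values are equal and approaches
#' 1 when one singular value dominates.
#'
#' @param J A non-zero numeric matrix.
#' @export
effective_dimension <- function(J) {
  s <- svd(J, nu = 0, nv = 0)$d
  if (max(s) == 0) stop("effective dimension undefined for the zero matrix")
  sum(s^2) / max(s)^2
}

#' Targeted dimensionality reduction axes
#'
#' Per time step and neuron, fits the linear model
#' `r = b_choice choice + b_inp1 u1 + b_inp2 u2 + b_context context + b_0`
#' across trials (u1, u2 are the per-trial signed strengths, context is
#' +1/-1). For each regressor the time of maximum coefficient-vector norm is
#' selected and the four peak vectors are orthonormalised by QR in the order
#' choice, input 1, input 2, context.
#'
#' @param rates N x trials x steps activity array (`phi(x)`), e.g. the
#'   `rates` field of [simulate_network()] with `record = "stimulus"`.
#' @param batch The `cdm_trials` batch that produced the activity.
#' @param choice Per-trial choice (+1/-1) from the simulation.
#' @return A `tdr_axes` object: `axes` (N x 4 orthonormal, named columns),
#'   `peak_times` (indices into the recorded steps), and `projections`, the
#'   condition-averaged trajectories (mean over trials sharing choice,
#'   context and input-1 strength) projected on the choice and input-1 axes.
#' @export
tdr_axes <- function(rates, batch, choice) {
  meta <- batch$meta
  X <- cbind(choice = choice, inp1 = meta$strength_loc,
             inp2 = meta$strength_frq,
             context = ifelse(meta$context == 1, 1, -1), intercept = 1)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient regressor matrix: need variation in all task variables")
  n_steps <- dim(rates)[3]
  N <- dim(rates)[1]
  XtXi <- solve(crossprod(X))
  betas <- array(0, c(N, 4, n_steps))
  for (t in seq_len(n_steps)) {
    Rt <- t(rates[, , t])                     # trials x N
    B <- XtXi %*% crossprod(X, Rt)            # 5 x N
    betas[, , t] <- t(B[1:4, , drop = FALSE])
  }
  norms <- apply(betas, c(2, 3), function(v) sqrt(sum(v^2)))
  peak <- apply(norms, 1, which.max)
  Bmax <- sapply(1:4, function(v) betas[, v, peak[v]])
  qrd <- qr(Bmax)
  axes <- qr.Q(qrd)
  # orient each axis along its regression vector
  for (j in 1:4) if (sum(axes[, j] * Bmax[, j]) < 0) axes[, j] <- -axes[, j]
  colnames(axes) <- c("choice", "input1", "input2", "context")
  cond <- interaction(choice, meta$context, meta$strength_loc, drop = TRUE)
  proj <- lapply(levels(cond), function(lv) {
    idx <- which(cond == lv)
    avg <- apply(rates[, idx, , drop = FALSE], c(1, 3), mean)  # N x steps
    data.frame(condition = lv,
               choice = choice[idx[1]], context = meta$context[idx[1]],
               strength_loc = meta$strength_loc[idx[1]],
               step = seq_len(n_steps),
               on_choice = drop(crossprod(axes[, "choice"], avg)),
               on_input1 = drop(crossprod(axes[, "input1"], avg)),
               n_trials = length(idx))
  })
  structure(list(axes = axes, peak_times = peak,
                 projections = do.call(rbind, proj)),
            class = "tdr_axes")
}

# build the shared convolutional design matrix for response-kernel regression;
# rows ordered time-within-trial: row = (k - 1) * T + t
.kernel_design <- function(batch) {
  cfg <- batch$config
  sti <- seq(cfg$n_fix + 1L, cfg$n_fix + cfg$n_sti)
  Tn <- cfg$n_sti
  K <- nrow(batch$u1)
  ctx <- batch$meta$context
  U <- list(batch$u1[, sti, drop = FALSE], batch$u2[, sti, drop = FALSE])
  eyeT <- diag(Tn)
  X_time <- kronecker(rep(1, K), eyeT)
  X_ctx <- kronecker(ifelse(ctx == 1, 1, 0), eyeT)
  conv_block <- function(Umat, gate) {
    out <- matrix(0, K * Tn, Tn)
    for (l in 0:(Tn - 1)) {
      shifted <- cbind(matrix(0, K, l), Umat[, seq_len(Tn - l), drop = FALSE])
      out[, l + 1] <- as.vector(t(shifted * gate))
    }
    out
  }
  g1 <- as.numeric(ctx == 1)
  g2 <- as.numeric(ctx == 2)
  list(Tn = Tn, K = K, sti = sti,
       X_time = X_time, X_ctx = X_ctx,
       conv = list(inp1_ctx1 = conv_block(U[[1]], g1),
                   inp1_ctx2 = conv_block(U[[1]], g2),
                   inp2_ctx1 = conv_block(U[[2]], g1),
                   inp2_ctx2 = conv_block(U[[2]], g2)))
}

#' Fit single-neuron pulse response kernels
#'
#' Ridge regression of each neuron's stimulus-period activity on per-time
#' choice, context and time regressors plus the convolution of a 40-step
#' response kernel with the signed pulse evidence of each input in each
#' context — 7 blocks of `n_sti` coefficients, i.e. 280 per neuron at the
#' default 40 stimulus steps. The design matrix is shared across neurons, so
#' one SVD solves all of them; the ridge strength is chosen by generalised
#' cross-validation over a log-spaced grid unless given numerically.
#'
#' @param rates N x trials x stimulus-steps activity array (from
#'   [simulate_network()] with `record = "stimulus"`).
#' @param batch The generating `cdm_trials` batch.
#' @param choice Per-trial choice (+1/-1).
#' @param ridge Numeric ridge strength, or `"gcv"` (default).
#' @return A `response_kernels` object: `kernels` (N x n_sti x 2 inputs x
#'   2 contexts), `aux` (choice/context/time coefficient matrices),
#'   `ridge` used, `n_coef` per neuron.
#' @export
fit_response_kernels <- function(rates, batch, choice, ridge = "gcv") {
  d <- .kernel_design(batch)
  Tn <- d$Tn; K <- d$K
  X_choice <- kronecker(matrix(choice, ncol = 1), diag(Tn))
  X <- cbind(X_choice, d$X_ctx, d$X_time,
             d$conv$inp1_ctx1, d$conv$inp1_ctx2,
             d$conv$inp2_ctx1, d$conv$inp2_ctx2)
  N <- dim(rates)[1]
  Y <- matrix(aperm(rates, c(3, 2, 1)), nrow = Tn * K, ncol = N)
  sv <- svd(X)
  UtY <- crossprod(sv$u, Y)
  if (identical(ridge, "gcv")) {
    grid <- 10^seq(-6, 2, by = 1)
    n <- nrow(X)
    yss <- sum(Y^2)
    gcv <- sapply(grid, function(lam) {
      f <- sv$d^2 / (sv$d^2 + lam)
      rss <- yss - sum((2 * f - f^2) * rowSums(UtY^2))
      rss / (1 - sum(f) / n)^2
    })
    ridge <- grid[which.min(gcv)]
  }
  if (!is.numeric(ridge) || ridge < 0) stop("invalid ridge strength")
  if (ridge == 0 && min(sv$d) < 1e-10 * max(sv$d))
    stop("singular design: a positive ridge strength is required")
  coef <- sv$v %*% ((sv$d / (sv$d^2 + ridge)) * UtY)   # 280 x N
  kern <- array(0, c(N, Tn, 2, 2),
                dimnames = list(NULL, NULL, c("inp1", "inp2"),
                                c("ctx1", "ctx2")))
  base <- 3 * Tn
  kern[, , 1, 1] <- t(coef[base + seq_len(Tn), ])
  kern[, , 1, 2] <- t(coef[base + Tn + seq_len(Tn), ])
  kern[, , 2, 1] <- t(coef[base + 2 * Tn + seq_len(Tn), ])
  kern[, , 2, 2] <- t(coef[base + 3 * Tn + seq_len(Tn), ])
  structure(list(kernels = kern,
                 aux = list(choice = t(coef[seq_len(Tn), ]),
                            context = t(coef[Tn + seq_len(Tn), ]),
                            time = t(coef[2 * Tn + seq_len(Tn), ])),
                 ridge = ridge, n_coef = nrow(coef)),
            class = "response_kernels")
}

#' SVD dynamical modes of the population response kernels
#'
#' Assembles the `n_sti` x 2N matrix `B` whose columns are every neuron's
#' response kernel for one input in each context, and decomposes it as
#' `B = U S V^T`. The first left singular vector is the persistent (choice)
#' mode; the remaining columns are transient dynamical modes. The normalised
#' explained variance of transient mode r is
#' `sigma_{r+1}^2 / sum_{i>=2} sigma_i^2`.
#'
#' @param kernels A `response_kernels` object.
#' @param input 1 or 2.
#' @return A `kernel_modes` object: `modes` (left singular vectors),
#'   `singular_values`, and `pev_transient` (normalised, over modes 1..T-1).
#' @export
kernel_modes <- function(kernels, input = 1) {
  stopifnot(inherits(kernels, "response_kernels"))
  B <- cbind(t(kernels$kernels[, , input, 1]), t(kernels$kernels[, , input, 2]))
  if (all(B == 0)) stop("all-zero kernel matrix")
  sv <- svd(B)
  d2 <- sv$d^2
  denom <- sum(d2[-1])
  pev <- if (denom > 0) d2[-1] / denom else rep(0, length(d2) - 1)
  structure(list(modes = sv$u, singular_values = sv$d,
                 pev_transient = pev, input = input),
            class = "kernel_modes")
}

#' Accumulated explained variance of extra dynamical modes
#'
#' Sums the normalised explained variance of the second and subsequent
#' transient dynamical modes — the population-level signature of
#' selection-vector modulation (a network whose kernels are spanned by the
#' decision-variable and sensory profiles needs only one transient mode).
#' `from_mode = 1` gives the literal sum over all transient modes (which is
#' identically 1 by normalisation) and exists for completeness.
#'
#' @param modes A `kernel_modes` object.
#' @param from_mode First transient mode included (default 2).
#' @return A value in [0, 1].
#' @export
pev_extra_modes <- function(modes, from_mode = 2) {
  stopifnot(inherits(modes, "kernel_modes"))
  p <- modes$pev_transient
  if (from_mode > length(p)) return(0)
  sum(p[from_mode:length(p)])
}
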