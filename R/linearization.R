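#' Find a slow point of the autonomous dynamics in one context
#'
#' Minimises the squared speed `||-x + J phi(x) + Ictx||^2` of the
#' input-free dynamics (context channel on) with L-BFGS-B from one or more
#' starting states, keeping the best solution. The default start is the
#' context embedding itself; additional starts (e.g. trajectory endpoints)
#' can be supplied.
#'
#' @param net A `network_params`.
#' @param context 1 or 2.
#' @param init_state Optional starting state or list of starting states.
#' @param tol Tolerance on the RMS (per-neuron) speed at the solution.
#'   Well-trained networks typically reach 1e-5 to 1e-4; the default flags
#'   genuine failures while tolerating the finite-size floor of large
#'   constructed networks.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return A `slow_point` list: `x`, `residual` (RMS speed), `context`.
#' @export
find_slow_point <- function(net, context, init_state = NULL, tol = 1e-3,
                            maxit = 1000) {
  stopifnot(inherits(net, "network_params"))
  if (tol <= 0) stop("tol must be positive")
  act <- .act_fun(net$activation)
  Ictx <- .ctx_embedding(net, context)
  N <- net$N
  speed_vec <- function(x) {
    ph <- act$phi(x)
    Jp <- if (net$lowrank) drop(net$m %*% (crossprod(net$n, ph) / N))
          else drop(net$J %*% ph)
    -x + Jp + Ictx
  }
  fn <- function(x) sum(speed_vec(x)^2)
  gr <- function(x) {
    v <- speed_vec(x)
    Jt_v <- if (net$lowrank) drop(net$n %*% (crossprod(net$m, v) / N))
            else drop(crossprod(net$J, v))
    2 * (-v + act$dphi(x) * Jt_v)
  }
  starts <- if (is.null(init_state)) list(Ictx)
            else if (is.list(init_state)) init_state else list(init_state)
  run <- function(x0) stats::optim(x0, fn, gr, method = "L-BFGS-B",
                                   control = list(maxit = maxit, factr = 1e4))
  best <- NULL
  for (x0 in starts) {
    opt <- run(x0)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (sqrt(best$value / N) > tol && is.null(init_state)) {
    # multi-start fallback: relax the input-free dynamics from Ictx and
    # re-optimise from the trajectory endpoints
    x <- Ictx
    a <- 20 / net$tau
    for (step in 1:400) {
      x <- x + a * speed_vec(x)
      if (step %in% c(100, 400)) {
        opt <- run(x)
        if (opt$value < best$value) best <- opt
      }
    }
  }
  res <- sqrt(best$value / N)
  if (res > tol)
    stop(sprintf("slow-point search failed in context %d: RMS speed %.3e > tol %.1e",
                 context, res, tol))
  structure(list(x = best$par, residual = res, context = context),
            class = "slow_point")
}

# gain diagonal at a state
.gain_at <- function(net, x) .act_fun(net$activation)$dphi(x)

# locate the line-attractor mode: the closest-to-zero *essentially real*
# eigenvalue. Complex (rotational) modes are never line-attractor candidates.
# Errors if a second real eigenvalue also sits inside the band (a genuinely
# ambiguous line attractor) or if the closest candidate is far from zero (no
# line attractor). Finite-size jitter may push the leading eigenvalue
# slightly outside the nominal band; the acceptance filter enforces the band
# itself.
.pick_near_zero <- function(lam, band, im_tol = 1e-6) {
  realish <- which(abs(Im(lam)) <= im_tol)
  if (!length(realish))
    stop("no approximate line attractor: all candidate modes are rotational")
  idx <- realish[which.min(abs(Re(lam[realish])))]
  in_band <- sum(abs(Re(lam[realish])) <= band)
  if (in_band > 1)
    stop("ambiguous line attractor: ", in_band,
         " real eigenvalues in the near-zero band [",
         paste(sprintf("%.4f", Re(lam[realish][abs(Re(lam[realish])) <= band])),
               collapse = ", "), "]")
  if (abs(Re(lam[idx])) > 6 * band)
    stop("no approximate line attractor: smallest |Re(eigenvalue)| = ",
         sprintf("%.4f", abs(Re(lam[idx]))))
  idx
}

# leading real part of the eigenvalues of M = -E + G J
.leading_eigenvalue <- function(net, x_star) {
  G <- .gain_at(net, x_star)
  if (net$lowrank) {
    mt <- net$m * G
    O <- crossprod(mt, net$n) / net$N   # O[r, q] = <G m_r, n_q>
    max(max(Re(eigen(O, only.values = TRUE)$values)) - 1, -1)
  } else {
    M <- -diag(net$N) + (G * net$J)
    max(Re(eigen(M, only.values = TRUE)$values))
  }
}

#' Linearise the dynamics around a slow point
#'
#' Computes the gain diagonal `G = phi'(x*)`, the transition matrix
#' `M = -E + G J` (kept implicit for low-rank networks), its eigenstructure,
#' and the line-attractor quantities: the unit-norm right eigenvector `rho`
#' of the unique near-zero eigenvalue, the selection vector `s` (left
#' eigenvector, scaled so `s . rho = 1`), and the input representation
#' directions `G I_s`. The sign of `rho` is fixed so that it has non-negative
#' overlap with the decision-variable representation direction (low-rank) or
#' the readout (full-rank), making directions comparable across contexts.
#'
#' For low-rank networks the nontrivial eigenstructure lives in the R
#' dimensional span of the connectivity vectors, so the eigenproblem is
#' solved on the R x R overlap matrix `O[r, q] = <G m_r, n_q>`; the remaining
#' eigenvalues equal -1.
#'
#' @param net A `network_params`.
#' @param slow_point A `slow_point` from [find_slow_point()], or a numeric
#'   state vector (e.g. the context embedding).
#' @param context Required when `slow_point` is a plain vector.
#' @param band Half-width of the near-zero eigenvalue band (default 0.05).
#' @return A `linearized_system` list: `context`, `x_star`, `gain`,
#'   `lambda_max`, `rho`, `s`, `Itilde1`, `Itilde2`.
#' @export
linearize <- function(net, slow_point, context = NULL, band = 0.05) {
  stopifnot(inherits(net, "network_params"))
  if (inherits(slow_point, "slow_point")) {
    x_star <- slow_point$x
    context <- slow_point$context
  } else {
    x_star <- slow_point
    if (is.null(context)) stop("context must be given with a raw state vector")
  }
  G <- .gain_at(net, x_star)
  N <- net$N
  if (net$lowrank) {
    mt <- net$m * G
    O <- crossprod(mt, net$n) / N
    # s = sum_r c_r n_r with O c = mu c;  rho = sum_r d_r (G m_r) with O^T d = mu d
    eo <- eigen(O)
    lam <- eo$values - 1
    idx <- .pick_near_zero(lam, band)
    if (abs(Im(lam[idx])) > 1e-8) stop("near-zero eigenvalue is complex")
    cvec <- Re(eo$vectors[, idx])        # s ~ sum_r c_r n_r
    s <- drop(net$n %*% cvec)
    er <- eigen(t(O))
    idx_r <- which.min(Mod(er$values - eo$values[idx]))
    dvec <- Re(er$vectors[, idx_r])      # rho ~ sum_r d_r (G m_r)
    rho <- drop(mt %*% dvec)
    lambda_max <- Re(lam[idx])
  } else {
    M <- -diag(N) + (G * net$J)
    ed <- eigen(M)
    lam <- ed$values
    idx <- .pick_near_zero(lam, band)
    if (abs(Im(lam[idx])) > 1e-6) stop("near-zero eigenvalue is complex")
    rho <- Re(ed$vectors[, idx])
    el <- eigen(t(M))
    idx_l <- which.min(Mod(el$values - lam[idx]))
    s <- Re(el$vectors[, idx_l])
    lambda_max <- Re(lam[idx])
  }
  rho <- rho / sqrt(sum(rho^2))
  ref <- if (net$lowrank && "dv" %in% colnames(net$m))
    G * net$m[, "dv"] else net$w
  if (sum(rho * ref) < 0) rho <- -rho
  s <- s / sum(s * rho)                 # enforce s . rho = 1
  structure(list(context = context, x_star = x_star, gain = G,
                 lambda_max = lambda_max, rho = rho, s = s,
                 Itilde1 = G * net$I1, Itilde2 = G * net$I2),
            class = "linearized_system")
}

# shared helper: linearized systems in both contexts
.linearize_both <- function(net, at = c("slow_point", "ctx_embedding"), ...) {
  at <- match.arg(at)
  lapply(1:2, function(ctx) {
    sp <- if (at == "slow_point") find_slow_point(net, ctx, ...)
          else .ctx_embedding(net, ctx)
    linearize(net, sp, context = ctx)
  })
}

#' Classical contextual-modulation decomposition
#'
#' Decomposes the contextual change of each input's integrated evidence,
#' `Delta(Itilde . s)`, into input modulation `Delta(Itilde) . s_bar` and
#' selection-vector modulation `Itilde_bar . Delta(s)`, where `Delta` is the
#' relevant-minus-irrelevant context difference (context 1 - context 2 for
#' input 1, the reverse for input 2) and the bar is the across-context mean.
#'
#' @param net A `network_params`.
#' @param at Linearise at the optimised slow point (default) or directly at
#'   the context embedding (the construction point of handcrafted networks).
#' @param ... Passed to [find_slow_point()].
#' @return A `modulation_decomposition` object: data frame `by_input` with
#'   columns input, mod_inp, mod_sel, proportion_sv; `combined` proportion
#'   from the summed components; `definition = "classical"`.
#' @export
classical_modulation <- function(net, at = c("slow_point", "ctx_embedding"),
                                 ...) {
  ls <- .linearize_both(net, at, ...)
  s1 <- ls[[1]]$s; s2 <- ls[[2]]$s
  sbar <- (s1 + s2) / 2; ds <- s1 - s2
  rows <- lapply(1:2, function(inp) {
    I_c1 <- if (inp == 1) ls[[1]]$Itilde1 else ls[[1]]$Itilde2
    I_c2 <- if (inp == 1) ls[[2]]$Itilde1 else ls[[2]]$Itilde2
    sgn <- if (inp == 1) 1 else -1      # relevant - irrelevant per input
    dI <- sgn * (I_c1 - I_c2)
    Ibar <- (I_c1 + I_c2) / 2
    mod_inp <- sum(dI * sbar)
    mod_sel <- sum(Ibar * (sgn * ds))
    data.frame(input = inp, mod_inp = mod_inp, mod_sel = mod_sel,
               proportion_sv = .safe_prop(mod_sel, mod_inp))
  })
  by_input <- do.call(rbind, rows)
  tot_inp <- sum(by_input$mod_inp); tot_sel <- sum(by_input$mod_sel)
  structure(list(by_input = by_input,
                 mod_inp = tot_inp, mod_sel = tot_sel,
                 proportion_sv = .safe_prop(tot_sel, tot_inp),
                 definition = "classical"),
            class = "modulation_decomposition")
}

.safe_prop <- function(mod_sel, mod_inp) {
  tot <- mod_sel + mod_inp
  if (abs(tot) < 1e-10) return(NA_real_)
  mod_sel / tot
}

#' @export
print.modulation_decomposition <- function(x, ...) {
  cat(sprintf("%s modulation decomposition\n", x$definition))
  print(x$by_input, row.names = FALSE)
  cat(sprintf("combined: mod_inp = %.4g, mod_sel = %.4g, proportion_sv = %.4g\n",
              x$mod_inp, x$mod_sel, x$proportion_sv))
  invisible(x)
}

#' Across-context cosines of selection vector and input representations
#'
#' @param net A `network_params`.
#' @param at See [classical_modulation()].
#' @param ... Passed to [find_slow_point()].
#' @return Named vector of cosines between context 1 and context 2 for the
#'   selection vector and the two input representation directions.
#' @export
representation_cosines <- function(net, at = c("slow_point", "ctx_embedding"),
                                   ...) {
  ls <- .linearize_both(net, at, ...)
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) stop("zero vector in cosine")
    sum(a * b) / (na * nb)
  }
  c(selection_vector = cosine(ls[[1]]$s, ls[[2]]$s),
    input1_representation = cosine(ls[[1]]$Itilde1, ls[[2]]$Itilde1),
    input2_representation = cosine(ls[[1]]$Itilde2, ls[[2]]$Itilde2))
}

#' Apply the (transposed) transition matrix to a vector
#'
#' Utility for identity checks such as `M^T n_tol ~ 0`: computes `M v` or
#' `M^T v` with `M = -E + G J` at the state `x_star`, without materialising
#' `M` for low-rank networks.
#'
#' @param net A `network_params`.
#' @param x_star State at which to evaluate the gain.
#' @param v Vector of length N.
#' @param transpose Apply `M^T` instead of `M`.
#' @export
transition_apply <- function(net, x_star, v, transpose = FALSE) {
  G <- .gain_at(net, x_star)
  if (net$lowrank) {
    mt <- net$m * G
    if (transpose) -v + drop(net$n %*% (crossprod(mt, v) / net$N))
    else -v + drop(mt %*% (crossprod(net$n, v) / net$N))
  } else {
    M <- -diag(net$N) + (G * net$J)
    if (transpose) drop(crossprod(M, v)) else drop(M %*% v)
  }
}
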