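#' Effective couplings between task variables
#'
#' For a low-rank network linearised at a state `x*` (by default the context
#' embedding, the construction point of the handcrafted networks), the
#' effective coupling from task variable `a` to internal variable `b` is the
#' gain-weighted overlap `E_{a->b} = <G rep_a, n_b>` with
#' `G = diag(phi'(x*))`; the representation vector `rep_a` is the input
#' embedding `I_s` for an input variable and the output vector `m_r` for an
#' internal variable. The constant terms `<n_b, phi(x*)>` are reported and a
#' warning is issued when they are not small (the linearisation around `x*`
#' is then unreliable).
#'
#' @param net A low-rank `network_params` whose last component is named
#'   `"dv"`.
#' @param context 1 or 2.
#' @param x_star Optional state; default is the context embedding. Pass a
#'   [find_slow_point()] result's `x` for trained networks.
#' @param const_warn Threshold on `|<n_b, phi(x*)>|` for the warning.
#' @return An `effective_couplings` object: matrix `E` (senders x
#'   receivers: `inp1`, `inp2` and the internal names as senders; internal
#'   names as receivers), `context`, `const` terms.
#' @export
effective_couplings <- function(net, context, x_star = NULL,
                                const_warn = 0.05) {
  stopifnot(inherits(net, "network_params"))
  if (!net$lowrank) stop("effective couplings require a low-rank network")
  if (is.null(x_star)) x_star <- .ctx_embedding(net, context)
  G <- .gain_at(net, x_star)
  internal <- colnames(net$m)
  senders <- c("inp1", "inp2", internal)
  reps <- cbind(net$I1, net$I2, net$m) * G
  E <- crossprod(reps, net$n) / net$N
  dimnames(E) <- list(senders, internal)
  const <- drop(crossprod(net$n, .act_fun(net$activation)$phi(x_star))) / net$N
  names(const) <- internal
  if (any(abs(const) > const_warn))
    warning("large constant term <n, phi(x*)>: linearisation may be unreliable")
  structure(list(E = E, context = context, const = const),
            class = "effective_couplings")
}

#' Information flow graph of a low-rank network in one context
#'
#' Orders the task variables as input variables, intermediate variables (the
#' internal components other than `dv`, in their stored order) and the
#' decision variable, and keeps every forward edge weighted by its effective
#' coupling, plus the decision variable's self-coupling.
#'
#' @param couplings An `effective_couplings` object, or a low-rank network
#'   (then `context` is required and couplings are computed at the context
#'   embedding).
#' @param context Context when `couplings` is a network.
#' @param tau Time constant stored for pulse-response evaluation.
#' @return A `flow_graph`: `nodes` (ordered; inputs first), `edges`
#'   (data frame from, to, weight), `E_dv_dv`, `context`, `tau`.
#' @export
flow_graph <- function(couplings, context = NULL, tau = 100) {
  if (inherits(couplings, "network_params")) {
    tau <- couplings$tau
    couplings <- effective_couplings(couplings, context)
  }
  stopifnot(inherits(couplings, "effective_couplings"))
  E <- couplings$E
  internal <- colnames(E)
  ivs <- setdiff(internal, "dv")
  inputs <- c("inp1", "inp2")
  nodes <- c(inputs, ivs, "dv")
  ord <- stats::setNames(seq_along(nodes), nodes)
  edges <- list()
  for (from in rownames(E)) for (to in internal) {
    if (from == "dv" || ord[[from]] >= ord[[to]]) next
    edges[[length(edges) + 1L]] <-
      data.frame(from = from, to = to, weight = E[from, to])
  }
  graph_from_edges(nodes, do.call(rbind, edges),
                   E_dv_dv = E["dv", "dv"], context = couplings$context,
                   tau = tau)
}

#' Build an information flow graph from an explicit edge list
#'
#' @param nodes Ordered node names; input nodes must come first (names
#'   starting with `"inp"`) and the last node must be `"dv"`.
#' @param edges Data frame with columns `from`, `to`, `weight`; edges must
#'   point forward in the node ordering.
#' @param E_dv_dv Self-coupling of the decision variable (default 1).
#' @param context Optional context label.
#' @param tau Time constant (ms).
#' @export
graph_from_edges <- function(nodes, edges, E_dv_dv = 1, context = NA,
                             tau = 100) {
  if (utils::tail(nodes, 1) != "dv") stop("last node must be 'dv'")
  ord <- stats::setNames(seq_along(nodes), nodes)
  if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes))
    stop("edge endpoints must be nodes")
  if (any(ord[edges$from] >= ord[edges$to]))
    stop("edges must point forward in the node ordering (DAG)")
  structure(list(nodes = nodes, edges = edges, E_dv_dv = E_dv_dv,
                 context = context, tau = tau,
                 inputs = nodes[startsWith(nodes, "inp")]),
            class = "flow_graph")
}

# all directed paths from `from` to `to`; returns list of node-name vectors
.enumerate_paths <- function(graph, from, to = "dv") {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    nxt <- graph$edges$to[graph$edges$from == last]
    for (v in nxt) walk(c(path, v))
  }
  walk(from)
  out
}

.edge_weight <- function(graph, from, to) {
  w <- graph$edges$weight[graph$edges$from == from & graph$edges$to == to]
  if (length(w) == 0) 0 else w[1]
}

.path_weight <- function(graph, path) {
  if (length(path) < 2) return(1)
  prod(vapply(seq_len(length(path) - 1),
              function(i) .edge_weight(graph, path[i], path[i + 1]), 0))
}

#' Total effective coupling from an input to the decision variable
#'
#' Sum over all forward paths of the product of edge couplings, computed by
#' dynamic programming over the node ordering.
#'
#' @param graph A `flow_graph`.
#' @param from Input node name (default `"inp1"`).
#' @export
total_effective_coupling <- function(graph, from = "inp1") {
  stopifnot(inherits(graph, "flow_graph"))
  val <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  val[from] <- 1
  for (v in graph$nodes[-seq_len(match(from, graph$nodes))]) {
    inc <- graph$edges[graph$edges$to == v, , drop = FALSE]
    if (nrow(inc)) val[v] <- sum(inc$weight * val[inc$from])
  }
  unname(val["dv"])
}

#' Pathway-based selection vector
#'
#' The pathway selection vector aggregates, over every route from the inputs
#' to the decision variable, the input-selection vector that performs the
#' first selection step, weighted by the product of downstream effective
#' couplings:
#' `n_tol = n_dv + sum_paths (E_{a1->a2} ... E_{aj->dv}) n_{iv_a1}`.
#' For a rank-1 network this reduces to `n_dv`; for the rank-3 circuits it is
#' `n_dv + E_{iv1->dv} n_{iv1} + E_{iv2->dv} n_{iv2}`.
#'
#' @param graph A `flow_graph` built from `net` (same context).
#' @param net The low-rank `network_params`.
#' @return A `pathway_sv` object: `n_tol`, `components` (one length-N vector
#'   per order: first order `n_dv`, second order the single-intermediate
#'   routes, etc.), `context`.
#' @export
pathway_selection_vector <- function(graph, net) {
  stopifnot(inherits(graph, "flow_graph"), inherits(net, "network_params"))
  internal <- colnames(net$n)
  if (!all(setdiff(graph$nodes, graph$inputs) %in% internal))
    stop("graph nodes do not match the network's internal variables")
  ivs <- setdiff(internal, "dv")
  comps <- list(order1 = net$n[, "dv"])
  for (iv in ivs) {
    for (p in .enumerate_paths(graph, iv)) {
      ord <- length(p)        # j edges -> order j + 1 component
      key <- paste0("order", ord)
      w <- .path_weight(graph, p)
      add <- w * net$n[, iv]
      comps[[key]] <- if (is.null(comps[[key]])) add else comps[[key]] + add
    }
  }
  comps <- comps[order(names(comps))]
  structure(list(n_tol = Reduce(`+`, comps), components = comps,
                 context = graph$context),
            class = "pathway_sv")
}

#' Pathway-based contextual-modulation decomposition
#'
#' Decomposes the contextual change of the total effective coupling,
#' `Delta E_tol`, path by path: writing each path's weight as the first edge
#' times the remaining product, `Delta(x y) = Delta(x) y_bar + x_bar Delta(y)`
#' splits every path into a component caused by the change of the stimulus
#' input representation (the first edge, whose sender is the input) — input
#' modulation — and the remainder — selection-vector modulation. `Delta` is
#' relevant minus irrelevant context (context 1 - 2 for input 1, the reverse
#' for input 2); bars are across-context means.
#'
#' @param net A low-rank `network_params`, or `NULL` when two graphs are
#'   supplied.
#' @param graphs Optional list of the two context `flow_graph`s (context 1
#'   first); computed from `net` at the context embeddings when missing.
#' @param inputs Input nodes to decompose (default both).
#' @return A `modulation_decomposition` (definition `"pathway"`), as in
#'   [classical_modulation()].
#' @export
pathway_modulation <- function(net = NULL, graphs = NULL, inputs = c(1, 2)) {
  if (is.null(graphs)) {
    stopifnot(inherits(net, "network_params"))
    graphs <- lapply(1:2, function(ctx) flow_graph(net, ctx))
  }
  g1 <- graphs[[1]]; g2 <- graphs[[2]]
  if (!identical(g1$nodes, g2$nodes))
    stop("the two context graphs must share their topology")
  rows <- lapply(inputs, function(inp) {
    from <- paste0("inp", inp)
    rel <- if (inp == 1) g1 else g2
    irr <- if (inp == 1) g2 else g1
    mod_inp <- 0; mod_sel <- 0
    for (p in .enumerate_paths(g1, from)) {
      x_rel <- .edge_weight(rel, p[1], p[2])
      x_irr <- .edge_weight(irr, p[1], p[2])
      rest <- p[-1]
      y_rel <- .path_weight(rel, rest)
      y_irr <- .path_weight(irr, rest)
      mod_inp <- mod_inp + (x_rel - x_irr) * (y_rel + y_irr) / 2
      mod_sel <- mod_sel + (x_rel + x_irr) / 2 * (y_rel - y_irr)
    }
    data.frame(input = inp, mod_inp = mod_inp, mod_sel = mod_sel,
               proportion_sv = .safe_prop(mod_sel, mod_inp))
  })
  by_input <- do.call(rbind, rows)
  tot_inp <- sum(by_input$mod_inp); tot_sel <- sum(by_input$mod_sel)
  structure(list(by_input = by_input, mod_inp = tot_inp, mod_sel = tot_sel,
                 proportion_sv = .safe_prop(tot_sel, tot_inp),
                 definition = "pathway"),
            class = "modulation_decomposition")
}

#' Closed-form latent pulse response
#'
#' For pulses `u_s(t) = A_s tau delta(t)` delivered at `t = 0` into an
#' information flow graph with unit decision-variable self-coupling, the
#' latent variables have closed forms: input variables decay as
#' `A exp(-t/tau)`; an intermediate variable is a sum over incoming path
#' lengths `j` of `K_j / j! exp(-t/tau) (t/tau)^j`; and the decision variable
#' accumulates `sum_j K_j P(j, t/tau)` with `P` the regularised lower
#' incomplete gamma function (so a j-edge path saturates as
#' `1 - Gamma(j, t/tau)/(j-1)!`), converging to the total effective coupling.
#'
#' @param graph A `flow_graph` (its `E_dv_dv` should be ~1 for the closed
#'   form to describe the network).
#' @param A Named vector of pulse sizes per input node (e.g.
#'   `c(inp1 = 1)`); unnamed scalars are applied to the first input.
#' @param t Vector of times (same unit as `graph$tau`, >= 0).
#' @return Matrix `length(t)` x nodes of latent values.
#' @export
pulse_response <- function(graph, A, t) {
  stopifnot(inherits(graph, "flow_graph"))
  if (any(t < 0)) stop("t must be >= 0")
  if (is.null(names(A))) {
    if (length(A) != 1) stop("A must be named per input node")
    A <- stats::setNames(A, graph$inputs[1])
  }
  z <- t / graph$tau
  out <- matrix(0, length(t), length(graph$nodes),
                dimnames = list(NULL, graph$nodes))
  for (inp in names(A)) {
    if (!inp %in% graph$inputs) stop("unknown input node: ", inp)
    out[, inp] <- out[, inp] + A[[inp]] * exp(-z)
    for (node in setdiff(graph$nodes, graph$inputs)) {
      paths <- .enumerate_paths(graph, inp, node)
      if (!length(paths)) next
      acc <- numeric(length(t))
      for (p in paths) {
        j <- length(p) - 1
        w <- .path_weight(graph, p)
        acc <- acc + if (node == "dv") w * stats::pgamma(z, shape = j)
                     else w / factorial(j) * exp(-z) * z^j
      }
      out[, node] <- out[, node] + A[[inp]] * acc
    }
  }
  out
}

#' Fine-step integration of the latent information-flow dynamics
#'
#' Numerical oracle for [pulse_response()]: integrates the linear latent
#' system (`tau k_inp' = -k_inp`, `tau k_iv' = -k_iv + sum E k`,
#' `tau k_dv' = -k_dv + sum E k + E_dv_dv k_dv`) from the pulse initial
#' condition `k_inp(0) = A`.
#'
#' @param graph A `flow_graph`.
#' @param A Named pulse sizes (as in [pulse_response()]).
#' @param dt Step size; `n_steps` steps are taken.
#' @param n_steps Number of steps.
#' @param method `"euler"` or `"rk4"` (high-accuracy oracle mode).
#' @return Matrix `(n_steps + 1)` x nodes of latent values (first row is
#'   `t = 0`), with attribute `times`.
#' @export
integrate_flow_ode <- function(graph, A, dt, n_steps,
                               method = c("rk4", "euler")) {
  method <- match.arg(method)
  nn <- graph$nodes
  W <- matrix(0, length(nn), length(nn), dimnames = list(nn, nn))
  for (i in seq_len(nrow(graph$edges)))
    W[graph$edges$to[i], graph$edges$from[i]] <- graph$edges$weight[i]
  W["dv", "dv"] <- graph$E_dv_dv
  k <- stats::setNames(numeric(length(nn)), nn)
  if (is.null(names(A))) A <- stats::setNames(A, graph$inputs[1])
  k[names(A)] <- A
  deriv <- function(k) (-k + drop(W %*% k)) / graph$tau
  out <- matrix(0, n_steps + 1, length(nn), dimnames = list(NULL, nn))
  out[1, ] <- k
  for (i in seq_len(n_steps)) {
    if (method == "euler") k <- k + dt * deriv(k)
    else {
      d1 <- deriv(k); d2 <- deriv(k + dt / 2 * d1)
      d3 <- deriv(k + dt / 2 * d2); d4 <- deriv(k + dt * d3)
      k <- k + dt / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
    }
    out[i + 1, ] <- k
  }
  attr(out, "times") <- dt * (0:n_steps)
  out
}

#' Discrete information-flow table
#'
#' Discretises the latent dynamics with a step equal to the time constant, so
#' information hops one edge per step: at step 1 the pulse contents sit in
#' the input slots; at each later step every slot holds the coupling-weighted
#' sum of its senders' previous contents, and the decision slot additionally
#' retains its own content through the (unit) self-coupling.
#'
#' @param graph A `flow_graph`.
#' @param pulses Named pulse sizes per input node.
#' @param n_steps Number of steps to tabulate.
#' @return Matrix `n_steps` x nodes of slot contents.
#' @export
discrete_flow <- function(graph, pulses, n_steps = 5) {
  stopifnot(inherits(graph, "flow_graph"))
  nn <- graph$nodes
  W <- matrix(0, length(nn), length(nn), dimnames = list(nn, nn))
  for (i in seq_len(nrow(graph$edges)))
    W[graph$edges$to[i], graph$edges$from[i]] <- graph$edges$weight[i]
  W["dv", "dv"] <- graph$E_dv_dv
  slot <- stats::setNames(numeric(length(nn)), nn)
  if (is.null(names(pulses))) pulses <- stats::setNames(pulses, graph$inputs[1])
  slot[names(pulses)] <- pulses
  out <- matrix(0, n_steps, length(nn), dimnames = list(NULL, nn))
  out[1, ] <- slot
  for (st in seq_len(n_steps - 1)) {
    slot <- drop(W %*% slot)
    out[st + 1, ] <- slot
  }
  out
}

#' Export a flow graph's edges as a data frame / CSV
#' @param graph A `flow_graph`.
#' @param path Optional CSV path.
#' @export
export_graph_edges <- function(graph, path = NULL) {
  df <- cbind(graph$edges, context = graph$context)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
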