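#' Rate-network parameter container
#'
#' Holds all connectivity, input, and readout parameters of one network. The
#' recurrent matrix is either full (`J`, N x N) or low rank, given by output
#' vectors `m_r` and input-selection vectors `n_r` with
#' `J = sum_r m_r n_r^T / N`. The four input embeddings correspond to the two
#' stimulus channels and the two context channels.
#'
#' @param I1,I2 Stimulus input embeddings (length N).
#' @param Ictx1,Ictx2 Context input embeddings (length N).
#' @param w Readout vector (length N); output is `mean(w * phi(x))`.
#' @param m,n N x R matrices of output / input-selection vectors (low-rank
#'   form), or `NULL` for a full-rank network.
#' @param J Full N x N connectivity matrix, or `NULL` for the low-rank form.
#' @param activation `"tanh"` (default) or `"softplus"`.
#' @param tau Neuron time constant in ms.
#' @param rank_names Optional names for the low-rank components (e.g.
#'   `c("iv1", "iv2", "dv")`); the decision-variable component must be named
#'   `"dv"` for pathway analyses.
#' @param meta Optional metadata list (recipe name, seed, parameters).
#' @return An object of class `network_params`.
#' @export
network_params <- function(I1, I2, Ictx1, Ictx2, w, m = NULL, n = NULL,
                           J = NULL, activation = "tanh", tau = 100,
                           rank_names = NULL, meta = list()) {
  N <- length(I1)
  for (v in list(I2, Ictx1, Ictx2, w))
    if (length(v) != N) stop("all embedding/readout vectors must have length N")
  if (!activation %in% c("tanh", "softplus")) stop("unknown activation")
  lowrank <- !is.null(m)
  if (lowrank) {
    m <- as.matrix(m); n <- as.matrix(n)
    if (nrow(m) != N || nrow(n) != N || ncol(m) != ncol(n) || ncol(m) < 1)
      stop("m and n must be N x R with R >= 1")
    if (is.null(rank_names)) {
      rank_names <- if (ncol(m) == 1) "dv" else
        c(paste0("iv", seq_len(ncol(m) - 1)), "dv")
    }
    colnames(m) <- colnames(n) <- rank_names
  } else {
    if (is.null(J) || !is.matrix(J) || any(dim(J) != N))
      stop("full-rank form requires an N x N matrix J")
  }
  structure(list(N = N, lowrank = lowrank,
                 I1 = as.numeric(I1), I2 = as.numeric(I2),
                 Ictx1 = as.numeric(Ictx1), Ictx2 = as.numeric(Ictx2),
                 w = as.numeric(w), m = m, n = n, J = J,
                 activation = activation, tau = tau, meta = meta),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  form <- if (x$lowrank) sprintf("rank-%d", ncol(x$m)) else "full-rank"
  cat(sprintf("network_params: N = %d, %s, activation = %s, tau = %g ms\n",
              x$N, form, x$activation, x$tau))
  if (!is.null(x$meta$recipe)) cat("  recipe:", x$meta$recipe, "\n")
  invisible(x)
}

#' Population overlap of two vectors
#'
#' The normalised inner product `<a, b> = mean(a * b)` used throughout for
#' effective couplings between task variables.
#' @param a,b Numeric vectors of equal length.
#' @export
overlap <- function(a, b) {
  stopifnot(length(a) == length(b))
  mean(a * b)
}

#' Materialise the connectivity matrix
#' @param net A `network_params` object.
#' @return The N x N matrix `J` (built as `m n^T / N` for low-rank nets).
#' @export
full_connectivity <- function(net) {
  stopifnot(inherits(net, "network_params"))
  if (!net$lowrank) return(net$J)
  tcrossprod(net$m, net$n) / net$N
}

.act_fun <- function(activation) {
  switch(activation,
         tanh = list(phi = tanh, dphi = function(x) 1 - tanh(x)^2),
         softplus = list(phi = function(x) log1p(exp(-abs(x))) + pmax(x, 0),
                         dphi = function(x) 1 / (1 + exp(-x))),
         stop("unknown activation"))
}

.ctx_embedding <- function(net, context) {
  if (context == 1) net$Ictx1 else net$Ictx2
}

.input_embedding <- function(net, input) {
  if (input == 1) net$I1 else net$I2
}

#' Serialise a network to a JSON container
#'
#' Writes every parameter vector/matrix plus the metadata attributes (N,
#' rank, activation, tau, provenance) to a versioned JSON file. The
#' round-trip `load_network(save_network(net, path))` restores every field to
#' full double precision.
#'
#' @param net A `network_params` object.
#' @param path Output file path.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "network_params"))
  payload <- list(container = "lowrankCDM-network", version = 1L,
                  N = net$N, lowrank = net$lowrank,
                  activation = net$activation, tau = net$tau,
                  I1 = net$I1, I2 = net$I2, Ictx1 = net$Ictx1,
                  Ictx2 = net$Ictx2, w = net$w, meta = net$meta)
  if (net$lowrank) {
    payload$rank_names <- colnames(net$m)
    payload$m <- net$m
    payload$n <- net$n
  } else {
    payload$J <- net$J
  }
  # digits = I(17): full 17 significant digits, exact double round-trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a network from its JSON container
#' @param path File written by [save_network()].
#' @export
load_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$container) || x$container != "lowrankCDM-network")
    stop("not a lowrankCDM network container")
  if (is.null(x$version) || x$version != 1L)
    stop("unsupported network container version: ", x$version)
  if (isTRUE(x$lowrank)) {
    network_params(x$I1, x$I2, x$Ictx1, x$Ictx2, x$w,
                   m = as.matrix(x$m), n = as.matrix(x$n),
                   activation = x$activation, tau = x$tau,
                   rank_names = x$rank_names,
                   meta = as.list(x$meta))
  } else {
    network_params(x$I1, x$I2, x$Ictx1, x$Ictx2, x$w, J = as.matrix(x$J),
                   activation = x$activation, tau = x$tau,
                   meta = as.list(x$meta))
  }
}
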