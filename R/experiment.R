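#' Run a named end-to-end experiment
#'
#' Reproducible pipelines tying the modules together. Each experiment seeds
#' R's RNG, runs the analysis, writes its tables as CSV into `out_dir`, and
#' writes a JSON manifest recording the name, configuration, seed, package
#' version and produced files.
#'
#' Available experiments:
#' \describe{
#'   \item{`build-rank3`}{Construct the pure selection-vector network and
#'     export its modulation decompositions.}
#'   \item{`family-grid`}{Grid over (alpha, beta, eta): classical vs pathway
#'     proportions (`decomp-compare` is an alias).}
#'   \item{`sv-compare`}{Random family networks: cosine between pathway and
#'     classical selection vectors in both contexts.}
#'   \item{`counterexample`}{Activity agreement and decomposition difference
#'     of the matched network pair.}
#'   \item{`train-rank1`}{Train rank-1 networks and export selection-vector
#'     cosines.}
#'   \item{`ensemble-fig7`}{Train a full-rank ensemble; export effective
#'     dimension, kernel-mode PEV and modulation proportion per network.}
#'   \item{`lesion`}{Task-irrelevant subspace PEV for trained networks and
#'     their redundant augmentations.}
#' }
#'
#' @param name Experiment name (see above).
#' @param config Named list of experiment parameters (sizes, counts, grids);
#'   unset entries fall back to desk-scale defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return The manifest (invisibly), a list with the output paths.
#' @export
run_experiment <- function(name, config = list(), out_dir = "results",
                           seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  cfg <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  files <- character(0)
  emit <- function(df, fname) {
    path <- file.path(out_dir, fname)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  if (name %in% c("family-grid", "decomp-compare")) {
    vals <- cfg("grid_values", c(0.1, 0.3, 0.5, 0.7, 0.9))
    N <- cfg("N", 3000)
    rows <- list()
    for (al in vals) for (be in vals) for (et in vals) {
      net <- build_rank3_family(al, be, et, N = N)
      pw <- pathway_modulation(net)
      cl <- classical_modulation(net, at = "ctx_embedding")
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = al, beta = be, eta = et,
        prop_pathway = pw$proportion_sv, prop_classical = cl$proportion_sv,
        prop_theory = be * et / (al + be * et))
    }
    if (!length(rows)) {
      warning("empty parameter grid: writing an empty table")
      rows <- list(data.frame(alpha = numeric(0), beta = numeric(0),
                              eta = numeric(0), prop_pathway = numeric(0),
                              prop_classical = numeric(0),
                              prop_theory = numeric(0)))
    }
    emit(do.call(rbind, rows), "family_grid.csv")
  } else if (name == "sv-compare") {
    n_nets <- cfg("n_networks", 100)
    N <- cfg("N", 3000)
    rows <- lapply(seq_len(n_nets), function(i) {
      th <- stats::runif(3)
      net <- build_rank3_family(th[1], th[2], th[3], N = N)
      cosines <- sapply(1:2, function(ctx) {
        g <- flow_graph(net, ctx)
        ntol <- pathway_selection_vector(g, net)$n_tol
        s <- linearize(net, .ctx_embedding(net, ctx), context = ctx)$s
        sum(ntol * s) / sqrt(sum(ntol^2) * sum(s^2))
      })
      data.frame(network = i, alpha = th[1], beta = th[2], eta = th[3],
                 cos_ctx1 = cosines[1], cos_ctx2 = cosines[2])
    })
    emit(do.call(rbind, rows), "sv_compare.csv")
  } else if (name == "build-rank3") {
    net <- build_rank3_pure_sv(N = cfg("N", 30000))
    cl <- classical_modulation(net, at = "ctx_embedding")
    pw <- pathway_modulation(net)
    emit(rbind(cbind(definition = "classical", cl$by_input),
               cbind(definition = "pathway", pw$by_input)),
         "rank3_pure_sv_decomposition.csv")
  } else if (name == "counterexample") {
    pair <- build_counterexample_pair(N = cfg("N", 30000))
    task <- task_config()
    batch <- sample_trials(task, cfg("n_trials", 5))
    s1 <- simulate_network(pair$rnn1, batch, record = "all")
    s2 <- simulate_network(pair$rnn2, batch, record = "all")
    p1 <- pathway_modulation(pair$rnn1)
    p2 <- pathway_modulation(pair$rnn2)
    emit(data.frame(max_abs_activity_diff = max(abs(s1$rates - s2$rates)),
                    prop_sv_rnn1 = p1$proportion_sv,
                    prop_sv_rnn2 = p2$proportion_sv),
         "counterexample.csv")
  } else if (name == "train-rank1") {
    n_nets <- cfg("n_networks", 2)
    tc <- train_config(N = cfg("N", 512), rank = 1,
                       steps = cfg("steps", 5000),
                       batch = cfg("batch", 256), w_reg = cfg("w_reg", 1e-4))
    rows <- lapply(seq_len(n_nets), function(i) {
      tm <- train_network(tc)
      cosines <- if (tm$accepted) representation_cosines(tm$net) else
        c(selection_vector = NA, input1_representation = NA,
          input2_representation = NA)
      data.frame(network = i, accepted = tm$accepted,
                 ev_ctx1 = tm$eigenvalues[1], ev_ctx2 = tm$eigenvalues[2],
                 t(cosines))
    })
    emit(do.call(rbind, rows), "rank1_training.csv")
  } else if (name == "ensemble-fig7") {
    grid <- cfg("grid", c(0.001, 0.01, 0.05, 0.1))
    ens <- train_ensemble(grid, cfg("n_per_value", 2),
                          train_config(N = cfg("N", 128), rank = "full",
                                       steps = cfg("steps", 2000),
                                       batch = cfg("batch", 128)))
    rows <- lapply(seq_along(ens$models), function(i) {
      tm <- ens$models[[i]]
      if (!tm$accepted)
        return(data.frame(network = i, accepted = FALSE, edim = NA,
                          prop_sv = NA, pev_extra = NA))
      idx <- signature_indices(tm$net, n_trials = cfg("n_trials", 500))
      data.frame(network = i, accepted = TRUE, edim = idx$edim,
                 prop_sv = idx$prop_sv, pev_extra = idx$pev_extra)
    })
    emit(cbind(ens$manifest, do.call(rbind, rows)), "ensemble.csv")
  } else if (name == "lesion") {
    n_pairs <- cfg("n_pairs", 3)
    tc <- train_config(N = cfg("N", 64), rank = "full",
                       steps = cfg("steps", 800), batch = cfg("batch", 64),
                       w_reg = cfg("w_reg", 1e-3))
    rows <- lapply(seq_len(n_pairs), function(i) {
      tm <- train_network(tc)
      red <- build_redundant(tm$net)
      p_orig <- pev_irrelevant_activity(irrelevant_subspace(tm$net))
      p_red <- pev_irrelevant_activity(irrelevant_subspace(red))
      data.frame(pair = i, pev_original = as.numeric(p_orig),
                 pev_redundant = as.numeric(p_red))
    })
    emit(do.call(rbind, rows), "lesion.csv")
  } else {
    stop("unknown experiment name: ", name)
  }
  manifest <- list(experiment = name, seed = seed, config = config,
                   package_version = as.character(utils::packageVersion("lowrankCDM")),
                   files = files, timestamp = format(Sys.time(), tz = "UTC"))
  mpath <- file.path(out_dir, paste0(gsub("[^a-z0-9]+", "_", name),
                                     "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  manifest$manifest_path <- mpath
  invisible(manifest)
}

#' Summary signature indices of a trained full-rank network
#'
#' Computes, for one network: the effective dimension of its connectivity,
#' the classical selection-vector modulation proportion, and the PEV of
#' extra dynamical modes from the response-kernel SVD (mean over the two
#' inputs).
#'
#' @param net A full-rank `network_params`.
#' @param task A [task_config()].
#' @param n_trials Trials used for the kernel regression.
#' @param ridge Ridge strength for [fit_response_kernels()].
#' @return List with `edim`, `prop_sv`, `pev_extra`.
#' @export
signature_indices <- function(net, task = task_config(), n_trials = 1000,
                              ridge = "gcv") {
  batch <- sample_trials(task, n_trials)
  sim <- simulate_network(net, batch, record = "stimulus")
  kern <- fit_response_kernels(sim$rates, batch, sim$choice, ridge = ridge)
  pev <- mean(sapply(1:2, function(inp)
    pev_extra_modes(kernel_modes(kern, inp))))
  cl <- classical_modulation(net)
  list(edim = effective_dimension(net$J), prop_sv = cl$proportion_sv,
       pev_extra = pev)
}
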