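# Smoke-scale full-rank ensemble for the signature-correlation check:
# 6 networks (3 regularisation values x 2) at N = 128, 3000 gradient steps,
# batch 64 — the largest configuration that fits a single-CPU run of the
# whole suite. Note these networks are far less converged than the
# reference protocol (5000 steps, batch 256), which the correlation claim
# conditions on; see the methods vignette.
fix_ensemble <- function() fixture("ensemble", function() {
  set.seed(880)
  nets <- list()
  rows <- list()
  for (wr in c(0.001, 0.01, 0.1)) for (i in 1:2) {
    tm <- train_network(train_config(N = 128, rank = "full", steps = 3000,
                                     batch = 64, w_reg = wr))
    idx <- tryCatch(signature_indices(tm$net, n_trials = 500),
                    error = function(e) list(edim = NA_real_,
                                             prop_sv = NA_real_,
                                             pev_extra = NA_real_))
    nets[[length(nets) + 1L]] <- tm$net
    rows[[length(rows) + 1L]] <- data.frame(
      w_reg = wr, replicate = i, accepted = tm$accepted,
      edim = idx$edim, prop_sv = idx$prop_sv, pev_extra = idx$pev_extra)
  }
  list(nets = nets, indices = do.call(rbind, rows))
})
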