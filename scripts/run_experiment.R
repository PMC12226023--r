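#!/usr/bin/env Rscript
# Thin command-line wrapper over lowrankCDM::run_experiment().
#
#   Rscript scripts/run_experiment.R --name family-grid --out results --seed 1
#   Rscript scripts/run_experiment.R --name ensemble-fig7 --config cfg.json
#
# --config points to a JSON file whose top-level keys are the experiment's
# parameters (sizes, counts, grids); --scale multiplies network/trial counts
# down for desk-scale runs where the experiment supports it.

suppressPackageStartupMessages({
  library(optparse)
  library(lowrankCDM)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--name", type = "character"),
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "results"),
  make_option("--seed", type = "integer", default = 1L)
)))

if (is.null(opts$name)) stop("--name is required")
config <- if (!is.null(opts$config))
  jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()

man <- run_experiment(opts$name, config = config, out_dir = opts$out,
                      seed = opts$seed)
cat("wrote:", paste(man$files, collapse = ", "), "\n")
cat("manifest:", man$manifest_path, "\n")
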