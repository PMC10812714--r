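#!/usr/bin/env Rscript

# Thin command-line front end over the popgenscan package.
#
#   Rscript scripts/popgenscan.R run-all --config run.yaml --out out_dir
#   Rscript scripts/popgenscan.R simulate --seed 7 --out-prefix sim/data
#
# Every analysis stage is an exported R function (apply_filters,
# diversity_summary, pairwise_matrix, sweep_scan, pair_r2/bin_decay/
# estimate_ne); run-all chains them from one YAML config.

suppressPackageStartupMessages({
  library(optparse)
  library(popgenscan)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1] %in% c("run-all", "simulate")) {
  cat("usage: popgenscan.R <run-all|simulate> [options]\n")
  quit(status = 2)
}
cmd <- args[1]
rest <- args[-1]

if (cmd == "run-all") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character"),
    make_option("--out", type = "character", default = "popgenscan_out"))),
    args = rest)
  if (is.null(o$config)) stop("run-all needs --config <yaml>")
  man <- run_all(o$config, o$out)
  quit(status = if (identical(man$status, "ok")) 0 else 1)
}

if (cmd == "simulate") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--seed", type = "integer", default = 1L),
    make_option("--config", type = "character", default = NULL),
    make_option("--out-prefix", type = "character", dest = "out_prefix",
                default = "simdata"))), args = rest)
  overrides <- if (!is.null(o$config)) yaml::read_yaml(o$config) else list()
  overrides$seed <- o$seed
  cfg <- do.call(sim_config, overrides)
  sim <- simulate_dataset(cfg, out_prefix = o$out_prefix)
  cat("wrote", unlist(sim$paths), sep = "\n  ")
  cat("\n")
}
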