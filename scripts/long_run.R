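#!/usr/bin/env Rscript
# Optional long job: the full-scale GEBV-vs-GPCP experiment (250 founders,
# 18 chromosomes, 40 cycles, per-cycle REML fits). Expect on the order of
# 1-3 hours per scenario on one CPU.
#
#   Rscript scripts/long_run.R [--seed N] [--mean-dd D] [--out FILE]

library(crosskit)

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
seed <- as.integer(get_arg("--seed", "1"))
mean_dd <- as.numeric(get_arg("--mean-dd", "2"))
out <- get_arg("--out", sprintf("trajectory_full_dd%g_seed%d.csv",
                                mean_dd, seed))

h2_for_dd <- c("0" = 0.6, "0.5" = 0.3, "1" = 0.3, "2" = 0.3, "4" = 0.1)
h2 <- h2_for_dd[[as.character(mean_dd)]]
if (is.null(h2)) h2 <- 0.3

cfg_path <- system.file("extdata", "config", "paper_scale.yaml",
                        package = "crosskit")
cfg <- read_sim_config(cfg_path)
cfg$mean_dd <- mean_dd
cfg$h2_trait <- h2

message(sprintf("full-scale run: mean_dd = %g, h2 = %g, seed = %d",
                mean_dd, h2, seed))
cli_simulate(cfg, seeds = seed, out = out)
message("wrote ", out)
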