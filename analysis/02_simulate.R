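#!/usr/bin/env Rscript

# Run the factorial Monte-Carlo experiment at desk scale: every scenario
# cell, all five analysis arms and all nine retention criteria, at a reduced
# replication count (the full design uses 1,000 replications per cell; 30
# keeps a complete single-core run within an afternoon while leaving the
# cell proportions interpretable to within ~0.09 Monte-Carlo error).
# Records land in results/run/records.csv with a JSON manifest; pass a
# number as the first argument to change the replication count.

library(retsim)

args <- commandArgs(trailingOnly = TRUE)
reps <- if (length(args)) as.integer(args[[1]]) else 30L

cfg <- default_config(reps = reps, master_seed = 42L)
cat(sprintf("running %d cells x %d replications x %d arms x %d criteria\n",
            8L, cfg$reps, length(cfg$arms), length(cfg$criteria)))
t0 <- proc.time()
records <- run_experiment(cfg, out_dir = "results/run", progress = TRUE)
elapsed <- (proc.time() - t0)[["elapsed"]]

ok <- mean(records$status == "ok")
cat(sprintf("\n%d records in %.1f min; %.2f%% evaluated cleanly\n",
            nrow(records), elapsed / 60, 100 * ok))
cat("slowest pieces are the tetrachoric arms of revised parallel analysis",
    "(each replication simulates ~100 comparison datasets per stage).\n")
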