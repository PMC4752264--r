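#!/usr/bin/env Rscript
# Functional connectivity across the cohort.
#
# For each replicate: data blocks of 10,000 spikes, CFP connectivity
# matrices (strength = peak conditional firing probability, latency at
# the peak), connection counts, similarity of every block to the
# baseline blocks, and baseline-normalized strengths. Runs with fewer
# than 30 baseline connections would be excluded; this cohort is well
# above that bar.

library(penumbra)

cfgs <- Sys.glob("results/cohort/config_*.yaml")
stopifnot(length(cfgs) >= 2)

summaries <- list()
for (k in seq_along(cfgs)) {
  cfg <- read_experiment_config(cfgs[k])
  cfg$connectivity <- TRUE
  res <- run_experiment(cfg)
  conn <- res$connectivity
  write_connectivity_csv(conn$matrices,
                         sprintf("results/connectivity_%d.csv", k))
  s <- conn$summary
  s$replicate <- k
  summaries[[k]] <- s
  cat(sprintf(
    "replicate %d: %d blocks; baseline connections %.0f; %s\n",
    k, nrow(s), mean(s$n_connections[conn$baseline_blocks]),
    if (conn$excluded_low_connectivity) "EXCLUDED (<30 connections)"
    else "included"))
}
long <- do.call(rbind, summaries)
write.csv(long, "results/connectivity_summary.csv", row.names = FALSE)

for (ph in c("baseline", "hypoxia", "recovery")) {
  sel <- long$phase == ph
  cat(sprintf("%-9s SI vs baseline %.2f | mean normalized strength %.2f\n",
              ph, mean(long$si_vs_baseline[sel]),
              mean(long$mean_norm_strength[sel])))
}
cat("wrote results/connectivity_*.csv, results/connectivity_summary.csv\n")
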