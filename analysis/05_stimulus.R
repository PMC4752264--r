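#!/usr/bin/env Rscript
# Synaptically mediated stimulus responses (A_syn) across the cohort.
#
# A_syn = area under the per-pulse-averaged post-stimulus response curve
# over 15-150 ms, per stimulation electrode per hourly block, normalized
# to its baseline value (electrodes with baseline A_syn < 6 spikes would
# be excluded). Writes the per-replicate series and the group summary.

library(penumbra)

cfgs <- Sys.glob("results/cohort/config_*.yaml")
stopifnot(length(cfgs) >= 2)

series <- list()
for (k in seq_along(cfgs)) {
  cfg <- read_experiment_config(cfgs[k])
  cfg$connectivity <- FALSE
  res <- run_experiment(cfg)
  a <- res$asyn
  a$replicate <- k
  series[[k]] <- a
  cat(sprintf("replicate %d: baseline A_syn %s; excluded electrodes: %d\n",
              k, paste(sprintf("%.1f", unique(a$asyn_baseline)),
                       collapse = ", "),
              sum(a$excluded) / max(1, length(unique(a$hour)))))
}
long <- do.call(rbind, series)
write.csv(long, "results/asyn_replicates.csv", row.names = FALSE)

# per-replicate electrode-mean series, then group mean +/- SEM per hour
per_rep <- lapply(series, function(a)
  aggregate(asyn_norm ~ hour, a[!a$excluded, ], mean))
grp <- summarize_group(per_rep, value = "asyn_norm", bin = "hour")
write.csv(grp, "results/asyn_group.csv", row.names = FALSE)
print(grp)

settled <- long$phase == "hypoxia" & long$hour >= 2
cat(sprintf("settled-hypoxia A_syn: %.2f of baseline (group mean)\n",
            mean(long$asyn_norm[settled], na.rm = TRUE)))
cat("wrote results/asyn_replicates.csv, results/asyn_group.csv\n")
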