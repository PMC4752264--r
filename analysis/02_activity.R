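#!/usr/bin/env Rscript
# Array-wide firing rate across the cohort.
#
# Recomputes the AWFR (30-min bins, normalized to the baseline mean) for
# each replicate, flags focally hyperactive electrodes, and writes the
# per-replicate series plus the group mean +/- SEM.

library(penumbra)

cfgs <- Sys.glob("results/cohort/config_*.yaml")
stopifnot(length(cfgs) >= 2)

series <- list()
for (k in seq_along(cfgs)) {
  cfg <- read_experiment_config(cfgs[k])
  cfg$connectivity <- FALSE
  res <- run_experiment(cfg)
  awfr <- res$awfr
  awfr$replicate <- k
  series[[k]] <- awfr
  focal <- res$focal_electrodes
  cat(sprintf("replicate %d: baseline mean %.0f spikes/bin; %s\n",
              k, attr(awfr, "baseline_mean"),
              if (length(focal)) paste("focal electrodes:",
                                       paste(focal, collapse = ", "))
              else "no focal electrodes"))
}
long <- do.call(rbind, series)
write.csv(long, "results/awfr_replicates.csv", row.names = FALSE)

grp <- summarize_group(lapply(series, function(d) d[d$complete, ]),
                       value = "normalized", bin = "bin_start_h")
write.csv(grp, "results/awfr_group.csv", row.names = FALSE)

hyp <- long$phase == "hypoxia" & long$complete & long$bin_start_h >= 2
cat(sprintf("settled-hypoxia AWFR: %.0f%% of baseline (group mean)\n",
            100 * mean(long$normalized[hyp])))
cat("wrote results/awfr_replicates.csv, results/awfr_group.csv\n")
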