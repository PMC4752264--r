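#!/usr/bin/env Rscript
# Simulate a small cohort of hypoxia experiments.
#
# Three replicate synthetic cultures run the scaled protocol (1-h normoxic
# baseline, 3-h severe hypoxia with synaptic efficacy and baseline rates
# at 50% of normoxia at the plateau, 2-h recovery; hourly 10-min
# stimulation blocks on two electrodes). Configs and spike tables go to
# results/; the later scripts regenerate the recordings deterministically
# from the configs.

library(penumbra)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

seeds <- c(101L, 202L, 303L)
for (k in seq_along(seeds)) {
  cfg <- experiment_config(seed = seeds[k], baseline_h = 1, hypoxia_h = 3,
                           recovery_h = 2, n_units = 30L,
                           efficacy_hypoxia = 0.5, rate_hypoxia = 0.5,
                           stim_electrodes = c(3L, 11L),
                           connectivity = FALSE)
  write_experiment_config(cfg, sprintf("results/cohort/config_%d.yaml", k))
  res <- run_experiment(cfg)
  write_spike_table(res$recording,
                    sprintf("results/cohort/spikes_%d.csv", k))
  cat(sprintf("replicate %d: %d spikes, %d electrodes active\n",
              k, nrow(res$recording$spikes),
              length(unique(res$recording$spikes$electrode))))
}
cat("cohort written to results/cohort/\n")
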