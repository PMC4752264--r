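#' Default experiment configuration
#'
#' A single serializable list holding the generator, protocol and
#' analysis parameters of one simulated hypoxia experiment. A run is
#' fully determined by its configuration (including the seed).
#'
#' @param seed master seed
#' @param baseline_h,hypoxia_h,recovery_h phase durations (hours)
#' @param n_units number of units (one per electrode)
#' @param efficacy_hypoxia,rate_hypoxia hypoxic-plateau multipliers
#' @param stim_electrodes electrodes stimulated every hour (NULL
#'   disables stimulation)
#' @param late_mean expected synaptically mediated spikes per pulse at
#'   efficacy 1
#' @param waveforms attach waveform cutouts (memory-heavy on long runs)
#' @param connectivity run per-block connectivity analysis
#' @param ... overrides stored verbatim in the config
#' @return nested list of class `experiment_config`
#' @export
experiment_config <- function(seed = 1L, baseline_h = 2, hypoxia_h = 6,
                              recovery_h = 3, n_units = 60L,
                              efficacy_hypoxia = 0.5, rate_hypoxia = 0.5,
                              stim_electrodes = c(5L, 23L),
                              late_mean = 8, waveforms = FALSE,
                              connectivity = TRUE, ...) {
  cfg <- list(
    seed = as.integer(seed),
    timeline = list(baseline_h = baseline_h, hypoxia_h = hypoxia_h,
                    recovery_h = recovery_h),
    network = list(n_units = as.integer(n_units), frac_inhibitory = 0.2,
                   n_tonic = 0L),
    protocol = list(pO2_baseline = 160, pO2_hypoxia = 23,
                    tau_down = 0.95, tau_up = 0.51,
                    efficacy_hypoxia = efficacy_hypoxia,
                    rate_hypoxia = rate_hypoxia),
    stimulation = list(electrodes = stim_electrodes,
                       pulses_per_block = 40L, ipi_range = c(5, 7),
                       late_mean = late_mean, early_mean = 2),
    analysis = list(awfr_bin_min = 30, block_size = 10000L,
                    active_min = 50L, tau_bin_ms = 0.5, tau_max_ms = 500,
                    alpha = 0.05, min_followers = 5L,
                    min_connections = 30L, asyn_min_baseline = 6,
                    fano_bin_s = 6),
    waveforms = waveforms,
    connectivity = connectivity
  )
  extra <- list(...)
  cfg[names(extra)] <- extra
  class(cfg) <- c("experiment_config", "list")
  cfg
}

#' Read / write an experiment configuration as YAML
#' @param path file path
#' @param config an [experiment_config()]
#' @return `read_experiment_config` returns the config list
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("experiment_config", "list")
  cfg
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run one simulated hypoxia experiment end to end
#'
#' Generates the synthetic recording defined by the configuration and
#' runs the full analysis battery: array-wide firing rate with focal
#' electrode flagging, per-block connectivity with similarity to
#' baseline and baseline-normalized strengths, the A_syn stimulus
#' series, and (when waveforms are attached) single-neuron screening
#' with Fano-factor classification. Identical configurations produce
#' identical bundles.
#'
#' @param config an [experiment_config()]
#' @return list of class `experiment_result`: `recording`, `awfr`,
#'   `focal_electrodes`, `connectivity` (matrices + summary with
#'   `si_vs_baseline` and `mean_norm_strength`), `asyn`, `units`,
#'   `config`
#' @export
run_experiment <- function(config) {
  tl <- phase_timeline(config$timeline$baseline_h,
                       config$timeline$hypoxia_h,
                       config$timeline$recovery_h)
  set.seed(config$seed)
  gt <- do.call(network_ground_truth, config$network)
  prot <- do.call(hypoxia_protocol, c(list(timeline = tl), config$protocol))
  sim_seed <- sample.int(.Machine$integer.max, 2L)

  stim <- config$stimulation$electrodes
  if (!is.null(stim) && length(stim)) {
    sched <- stimulation_schedule(stim, n_hours = floor(total_hours(tl)),
                                  pulses_per_block = config$stimulation$pulses_per_block,
                                  ipi_range = config$stimulation$ipi_range)
    rec <- simulate_stimulus_responses(
      gt, sched, prot, seed = sim_seed[1],
      kernel = response_kernel(early_mean = config$stimulation$early_mean,
                               late_mean = config$stimulation$late_mean),
      waveforms = isTRUE(config$waveforms))
  } else {
    rec <- simulate_spontaneous(gt, prot, seed = sim_seed[1],
                                waveforms = isTRUE(config$waveforms))
  }

  awfr <- compute_awfr(rec, bin_min = config$analysis$awfr_bin_min)
  focal <- flag_focal_electrodes(rec)

  conn <- NULL
  if (isTRUE(config$connectivity)) {
    conn <- connectivity_series(
      rec, block_size = config$analysis$block_size,
      active_min = config$analysis$active_min,
      tau_bin_ms = config$analysis$tau_bin_ms,
      tau_max_ms = config$analysis$tau_max_ms,
      alpha = config$analysis$alpha,
      min_followers = config$analysis$min_followers)
    base_idx <- which(conn$summary$phase == "baseline")
    insufficient <- length(base_idx) == 0L ||
      mean(conn$summary$n_connections[base_idx]) <
        config$analysis$min_connections
    conn$baseline_blocks <- base_idx
    conn$excluded_low_connectivity <- insufficient
    if (length(base_idx)) {
      conn$summary$si_vs_baseline <- vapply(seq_along(conn$matrices),
        function(b) {
          sis <- vapply(base_idx, function(a) suppressWarnings(
            similarity_index(conn$matrices[[a]], conn$matrices[[b]])),
            numeric(1))
          mean(sis, na.rm = FALSE)
        }, numeric(1))
      ns <- normalize_strengths(conn$matrices, base_idx)
      conn$baseline_mean <- ns$baseline_mean
      conn$new_connections <- ns$new_connections
      conn$matrices <- ns$matrices
      base_set <- ns$baseline_mean > 0
      conn$summary$mean_norm_strength <- vapply(conn$matrices, function(m)
        mean(m$S_norm[base_set]), numeric(1))
    }
  }

  asyn <- NULL
  if (!is.null(rec$schedule)) {
    asyn <- normalize_asyn(asyn_series(rec),
                           min_baseline = config$analysis$asyn_min_baseline)
  }

  units <- NULL
  if (!is.null(rec$waveforms)) {
    present <- sort(unique(rec$spikes$electrode))
    screens <- lapply(present, function(e) single_neuron_screen(rec, e))
    single <- present[vapply(screens, `[[`, logical(1), "is_single_neuron")]
    fates <- vapply(single, function(e) {
      tr <- tryCatch(track_shape(rec, e), error = function(err) NULL)
      if (is.null(tr)) NA_character_
      else assign_fate(tr, floor(rec$duration_h))$fate
    }, character(1))
    names(fates) <- as.character(single)
    units <- unit_profiles(rec, single, fates = fates,
                           bin_s = config$analysis$fano_bin_s)
  }

  structure(list(recording = rec, awfr = awfr, focal_electrodes = focal,
                 connectivity = conn, asyn = asyn, units = units,
                 config = config),
            class = "experiment_result")
}

#' Group summary: mean and SEM per time bin across replicates
#'
#' Normalization happens per replicate (inside each series) before
#' averaging; this routine only aligns replicate series on a common bin
#' column and returns mean +/- SEM per bin.
#'
#' @param series_list list of data.frames (>= 2), one per replicate
#' @param value name of the value column
#' @param bin name of the bin/time column
#' @return data.frame: bin column, `n`, `mean`, `sem`
#' @export
summarize_group <- function(series_list, value, bin) {
  if (length(series_list) < 2L)
    stop("need >= 2 replicates for a group summary (SEM undefined)")
  long <- do.call(rbind, lapply(seq_along(series_list), function(k) {
    d <- series_list[[k]]
    data.frame(bin = d[[bin]], value = d[[value]], rep = k)
  }))
  long <- long[!is.na(long$value), ]
  agg <- do.call(rbind, lapply(split(long, long$bin), function(d)
    data.frame(bin = d$bin[1], n = nrow(d), mean = mean(d$value),
               sem = stats::sd(d$value) / sqrt(nrow(d)))))
  names(agg)[1] <- bin
  rownames(agg) <- NULL
  agg[order(agg[[bin]]), ]
}
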