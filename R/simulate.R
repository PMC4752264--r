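#' @import data.table
NULL

new_recording <- function(spikes, ground_truth, protocol, duration_h,
                          schedule = NULL, waveforms = NULL, fs = 16000) {
  ord <- order(spikes$time_s, spikes$electrode)
  spikes <- spikes[ord, , drop = FALSE]
  rownames(spikes) <- NULL
  if (!is.null(waveforms)) waveforms <- waveforms[ord, , drop = FALSE]
  structure(list(
    spikes = spikes,
    waveforms = waveforms,
    n_electrodes = if (!is.null(ground_truth)) ground_truth$n_electrodes else 60L,
    duration_h = duration_h,
    timeline = if (!is.null(protocol)) protocol$timeline else NULL,
    protocol = protocol,
    schedule = schedule,
    ground_truth = ground_truth,
    fs = fs
  ), class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d spikes on %d electrodes, %.2f h\n",
              nrow(x$spikes), x$n_electrodes, x$duration_h))
  if (!is.null(x$timeline)) {
    ph <- apply(x$timeline, 1, function(r)
      sprintf("%s %.4g-%.4g h", r[["phase"]],
              as.numeric(r[["start_h"]]), as.numeric(r[["end_h"]])))
    cat("  timeline:", paste(ph, collapse = ", "), "\n")
  }
  if (!is.null(x$schedule))
    cat("  stimulation:", nrow(x$schedule), "pulses on electrodes",
        paste(unique(x$schedule$electrode), collapse = ", "), "\n")
  if (!is.null(x$waveforms)) cat("  waveform cutouts attached\n")
  invisible(x)
}

silenced_after <- function(protocol, units, t_h) {
  on <- protocol$silencing_onset_h
  if (is.null(on)) return(rep(FALSE, length(units)))
  o <- on[units]
  !is.na(o) & t_h >= o
}

# Baseline (generation-0) spikes for all units: inhomogeneous Poisson by
# thinning for excitatory/intrinsic units, burst process for inhibitory.
base_spikes <- function(gt, protocol, T_s) {
  times <- list(); units <- list(); k <- 0L
  for (u in seq_len(gt$n_units)) {
    cls <- gt$unit_class[u]
    if (cls == "inhibitory") {
      n_on <- stats::rpois(1, gt$burst_rate_per_h * T_s / 3600)
      t_on <- sort(stats::runif(n_on, 0, T_s))
      t_on <- t_on[stats::runif(n_on) < rate_mult_at(protocol, t_on / 3600)]
      tt <- if (length(t_on)) {
        counts <- stats::rpois(length(t_on), gt$burst_size)
        rep(t_on, counts) + stats::runif(sum(counts), 0, gt$burst_duration_s)
      } else numeric(0)
      nq <- stats::rpois(1, gt$quiet_rate * T_s)
      tq <- stats::runif(nq, 0, T_s)
      tq <- tq[stats::runif(length(tq)) < rate_mult_at(protocol, tq / 3600)]
      tt <- c(tt, tq)
    } else {
      n <- stats::rpois(1, gt$base_rate[u] * T_s)
      tt <- stats::runif(n, 0, T_s)
      if (cls != "intrinsic")  # tonic units escape hypoxic rate suppression
        tt <- tt[stats::runif(length(tt)) < rate_mult_at(protocol, tt / 3600)]
    }
    tt <- tt[tt < T_s]
    tt <- tt[!silenced_after(protocol, rep(u, length(tt)), tt / 3600)]
    if (length(tt)) {
      k <- k + 1L
      times[[k]] <- tt
      units[[k]] <- rep(u, length(tt))
    }
  }
  list(time_s = unlist(times) %||% numeric(0),
       unit = unlist(units) %||% integer(0))
}

# One branching generation: each parent spike of unit i triggers a child
# on unit j with probability strength * efficacy(t) at the edge delay.
branch_once <- function(gt, protocol, times, units, T_s, jitter_ms) {
  if (!nrow(gt$edges) || !length(times))
    return(list(time_s = numeric(0), unit = integer(0)))
  out_t <- list(); out_u <- list(); k <- 0L
  idx_by_unit <- split(seq_along(units), units)
  for (e in seq_len(nrow(gt$edges))) {
    par <- idx_by_unit[[as.character(gt$edges$from[e])]]
    if (is.null(par)) next
    tp <- times[par]
    p <- gt$edges$strength[e] * efficacy_at(protocol, tp / 3600)
    hit <- stats::runif(length(tp)) < p
    if (!any(hit)) next
    tc <- tp[hit] + (gt$edges$delay_ms[e] +
                       stats::rnorm(sum(hit), 0, jitter_ms)) / 1000
    keep <- tc > tp[hit] & tc < T_s
    tc <- tc[keep]
    uc <- rep(gt$edges$to[e], length(tc))
    drop <- silenced_after(protocol, uc, tc / 3600)
    tc <- tc[!drop]; uc <- uc[!drop]
    if (length(tc)) {
      k <- k + 1L
      out_t[[k]] <- tc
      out_u[[k]] <- uc
    }
  }
  list(time_s = unlist(out_t) %||% numeric(0),
       unit = unlist(out_u) %||% integer(0))
}

#' Simulate spontaneous activity of a coupled culture
#'
#' Conditionally Poisson point-process model on a 60-electrode array. Each
#' unit fires a baseline train (near-Poisson for excitatory units, rare
#' intense bursts for inhibitory units, tonic for intrinsically active
#' ones) whose intensity is scaled by the protocol's hypoxic rate
#' multiplier. Directed coupling is a branching process: every spike of
#' unit i independently triggers a spike of unit j with probability
#' `adjacency[i,j] * efficacy(t)` at the edge delay (Gaussian jitter,
#' default SD 0.1 ms). Cascades propagate until extinction. A 1-ms
#' per-unit refractory period is enforced on the merged train.
#'
#' Every spike carries its ground-truth source unit. With
#' `waveforms = TRUE` each spike also carries a 96-sample cutout equal to
#' the unit template (morphed past the unit's deformation onset, if any)
#' plus i.i.d. Gaussian noise.
#'
#' @param ground_truth a [network_ground_truth()]
#' @param protocol a [hypoxia_protocol()]
#' @param duration_h recording length (hours); defaults to the protocol
#'   timeline's total span
#' @param seed integer seed (required: recordings are reproducible)
#' @param waveforms attach per-spike waveform cutouts?
#' @param waveform_noise_sd additive noise SD on cutouts (uV)
#' @param jitter_ms SD of synaptic-delay jitter (ms)
#' @param max_generations cascade depth guard
#' @return an `mea_recording` with spike table columns
#'   `time_s`, `electrode`, `unit`, `evoked`
#' @export
simulate_spontaneous <- function(ground_truth, protocol,
                                 duration_h = total_hours(protocol$timeline),
                                 seed, waveforms = FALSE,
                                 waveform_noise_sd = 3, jitter_ms = 0.1,
                                 max_generations = 30L) {
  if (is.null(ground_truth) || ground_truth$n_units < 1)
    stop("empty ground truth")
  if (!is.numeric(duration_h) || duration_h <= 0)
    stop("duration_h must be positive")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  T_s <- duration_h * 3600

  g <- base_spikes(ground_truth, protocol, T_s)
  all_t <- g$time_s; all_u <- g$unit
  gen <- 0L
  while (length(g$time_s) && gen < max_generations) {
    g <- branch_once(ground_truth, protocol, g$time_s, g$unit, T_s, jitter_ms)
    all_t <- c(all_t, g$time_s)
    all_u <- c(all_u, g$unit)
    gen <- gen + 1L
  }

  keep <- refractory_keep(all_t, all_u)
  all_t <- all_t[keep]; all_u <- all_u[keep]
  spikes <- data.frame(time_s = all_t,
                       electrode = ground_truth$unit_electrode[all_u],
                       unit = all_u,
                       evoked = FALSE)
  W <- NULL
  if (waveforms)
    W <- spike_waveform_matrix(ground_truth, protocol, spikes,
                               noise_sd = waveform_noise_sd)
  new_recording(spikes, ground_truth, protocol, duration_h,
                waveforms = W)
}

# Cutouts = unit template (morphed if past the unit's deformation onset)
# plus i.i.d. Gaussian noise; rows aligned with `spikes`.
spike_waveform_matrix <- function(gt, protocol, spikes, noise_sd = 3) {
  n <- nrow(spikes)
  W <- matrix(stats::rnorm(n * 96, 0, noise_sd), n, 96)
  morph_on <- protocol$morph_onset_h
  for (u in unique(spikes$unit)) {
    rows <- which(spikes$unit == u)
    on <- if (is.null(morph_on)) NA_real_ else morph_on[u]
    if (is.na(on)) {
      W[rows, ] <- W[rows, , drop = FALSE] +
        matrix(gt$template[u, ], length(rows), 96, byrow = TRUE)
    } else {
      for (r in rows) {
        past <- spikes$time_s[r] / 3600 - on
        W[r, ] <- W[r, ] + morph_template(gt$template[u, ], past)
      }
    }
  }
  W
}

#' Hourly stimulation schedule
#'
#' Each clock hour starts with a 10-min stimulation segment in which the
#' selected electrodes are stimulated in random order, `pulses_per_block`
#' pulses each, at inter-pulse intervals drawn uniformly from `ipi_range`.
#'
#' @param stim_electrodes electrode ids used for stimulation (typically
#'   2-3)
#' @param n_hours number of clock hours covered
#' @param pulses_per_block pulses per electrode per hourly block
#' @param ipi_range inter-pulse interval range (s); must keep the whole
#'   block within the 10-min segment
#' @param stim_min stimulation segment length (minutes)
#' @return data.frame (`time_s`, `electrode`, `hour`) of class
#'   `stimulation_schedule`, pulse times strictly increasing
#' @export
stimulation_schedule <- function(stim_electrodes, n_hours,
                                 pulses_per_block = 40L,
                                 ipi_range = c(5, 7), stim_min = 10) {
  stopifnot(length(stim_electrodes) >= 1, n_hours >= 1,
            ipi_range[1] >= 0, diff(ipi_range) >= 0)
  worst <- length(stim_electrodes) * pulses_per_block * ipi_range[2]
  if (worst > stim_min * 60)
    stop("schedule cannot fit in the ", stim_min, "-min stimulation segment")
  out <- vector("list", n_hours)
  for (h in seq_len(n_hours) - 1L) {
    order_e <- if (length(stim_electrodes) == 1L) stim_electrodes
               else sample(stim_electrodes)
    el <- rep(order_e, each = pulses_per_block)
    ipi <- stats::runif(length(el), ipi_range[1], ipi_range[2])
    out[[h + 1L]] <- data.frame(
      time_s = h * 3600 + cumsum(ipi),
      electrode = el,
      hour = h
    )
  }
  sched <- do.call(rbind, out)
  attr(sched, "pulses_per_block") <- pulses_per_block
  attr(sched, "ipi_range") <- ipi_range
  class(sched) <- c("stimulation_schedule", "data.frame")
  sched
}

#' Stimulus-response kernel
#'
#' Expected evoked spikes per pulse, split into the early direct component
#' (latency < 15 ms, not synaptically mediated, independent of hypoxic
#' efficacy) and the late synaptically mediated component (15-150 ms) whose
#' expected count scales with the protocol's efficacy multiplier.
#'
#' @param early_mean expected array-wide direct spikes per pulse
#' @param late_mean expected array-wide synaptically mediated spikes per
#'   pulse at efficacy 1
#' @param early_window_ms,late_window_ms latency support (ms)
#' @return list of class `response_kernel`
#' @export
response_kernel <- function(early_mean = 2, late_mean = 8,
                            early_window_ms = c(2, 15),
                            late_window_ms = c(15, 150)) {
  structure(list(early_mean = early_mean, late_mean = late_mean,
                 early_window_ms = early_window_ms,
                 late_window_ms = late_window_ms),
            class = "response_kernel")
}

#' Simulate a recording with stimulus-evoked responses
#'
#' Superimposes evoked spikes on a spontaneous simulation. For each pulse,
#' the early direct response count is Poisson with mean
#' `kernel$early_mean`, and the late synaptically mediated count is
#' Poisson with mean `kernel$late_mean * efficacy(t)`; latencies are drawn
#' inside the kernel windows and spikes assigned to random units. The
#' merged train is time-sorted with the 1-ms refractory rule re-applied.
#'
#' @inheritParams simulate_spontaneous
#' @param schedule a [stimulation_schedule()]
#' @param kernel a [response_kernel()]; all-zero means reproduce the
#'   spontaneous-only law
#' @return an `mea_recording`; evoked spikes carry `evoked = TRUE`
#' @export
simulate_stimulus_responses <- function(ground_truth, schedule, protocol,
                                        duration_h = total_hours(protocol$timeline),
                                        seed, kernel = response_kernel(),
                                        waveforms = FALSE,
                                        waveform_noise_sd = 3,
                                        jitter_ms = 0.1) {
  if (max(schedule$time_s) > duration_h * 3600)
    stop("stimulation schedule extends beyond the recording duration")
  rec <- simulate_spontaneous(ground_truth, protocol, duration_h,
                              seed = seed, waveforms = FALSE,
                              jitter_ms = jitter_ms)
  n_units <- ground_truth$n_units
  ev_t <- list(); ev_u <- list(); k <- 0L
  for (p in seq_len(nrow(schedule))) {
    tp <- schedule$time_s[p]
    eff <- efficacy_at(protocol, tp / 3600)
    n_early <- stats::rpois(1, kernel$early_mean)
    n_late <- stats::rpois(1, kernel$late_mean * eff)
    lat <- c(stats::runif(n_early, kernel$early_window_ms[1],
                          kernel$early_window_ms[2]),
             kernel$late_window_ms[1] + diff(kernel$late_window_ms) *
               stats::rbeta(n_late, 2, 2.5))
    if (!length(lat)) next
    k <- k + 1L
    ev_t[[k]] <- tp + lat / 1000
    ev_u[[k]] <- sample.int(n_units, length(lat), replace = TRUE)
  }
  if (k > 0L) {
    ev <- data.frame(time_s = unlist(ev_t),
                     electrode = ground_truth$unit_electrode[unlist(ev_u)],
                     unit = unlist(ev_u),
                     evoked = TRUE)
    ev <- ev[ev$time_s < duration_h * 3600, , drop = FALSE]
    sil <- silenced_after(protocol, ev$unit, ev$time_s / 3600)
    ev <- ev[!sil, , drop = FALSE]
    spikes <- rbind(rec$spikes, ev)
    keep <- refractory_keep(spikes$time_s, spikes$unit)
    spikes <- spikes[keep, , drop = FALSE]
  } else {
    spikes <- rec$spikes
  }
  W <- NULL
  if (waveforms)
    W <- spike_waveform_matrix(ground_truth, protocol, spikes,
                               noise_sd = waveform_noise_sd)
  new_recording(spikes, ground_truth, protocol, duration_h,
                schedule = schedule, waveforms = W)
}

#' Render raw voltage traces from a recording
#'
#' Sums each unit's waveform template at its spike times on the unit's
#' electrode and adds i.i.d. Gaussian noise, producing per-electrode
#' sampled traces at 16 kHz for end-to-end testing of threshold-based
#' spike detection. Overlapping template placements are summed.
#'
#' @param recording an `mea_recording` with ground truth
#' @param noise_sd Gaussian noise SD (uV, >= 0)
#' @param seed integer seed for the noise draw
#' @param electrodes electrodes to render (default: all with spikes)
#' @param fs sample rate (Hz)
#' @return named list of numeric traces (one per electrode), with
#'   attributes `fs` and `noise_sd`
#' @export
render_raw_traces <- function(recording, noise_sd, seed,
                              electrodes = NULL, fs = 16000) {
  if (noise_sd < 0) stop("negative noise_sd")
  gt <- recording$ground_truth
  if (is.null(gt)) stop("recording carries no ground-truth templates")
  set.seed(seed)
  n_samp <- ceiling(recording$duration_h * 3600 * fs)
  if (is.null(electrodes)) electrodes <- sort(unique(recording$spikes$electrode))
  traces <- vector("list", length(electrodes))
  names(traces) <- as.character(electrodes)
  for (i in seq_along(electrodes)) {
    e <- electrodes[i]
    tr <- stats::rnorm(n_samp, 0, noise_sd)
    sp <- recording$spikes[recording$spikes$electrode == e, , drop = FALSE]
    for (r in seq_len(nrow(sp))) {
      u <- sp$unit[r]
      peak <- round(sp$time_s[r] * fs) + 1L
      lo <- peak - 32L; hi <- peak + 63L
      wlo <- max(1L, lo); whi <- min(n_samp, hi)
      if (wlo > whi) next
      tr[wlo:whi] <- tr[wlo:whi] +
        gt$template[u, (wlo - lo + 1L):(96L - (hi - whi))]
    }
    traces[[i]] <- tr
  }
  attr(traces, "fs") <- fs
  attr(traces, "noise_sd") <- noise_sd
  traces
}
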