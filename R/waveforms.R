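#' Waveform variability of an electrode's spike cutouts
#'
#' Computes the single-neuron variability statistic on a set of
#' amplitude-normalized 96-sample cutouts. With `Mean_AP[n]` and
#' `SD_AP[n]` the per-sample mean and standard deviation over cutouts
#' (computed after dividing every cutout by the peak absolute value of
#' the raw mean waveform), the statistic is
#'
#'   variability = | sum_{n=9}^{59} SD_AP[n] * Mean_AP[n] / 51 | / max|Mean_AP|
#'
#' The 9-59 sample window spans 1.5 ms before to ~1.6 ms after the peak
#' (sample 33), so shape differences near the peak dominate. The
#' amplitude normalization makes the statistic dimensionless; identical
#' cutouts give exactly 0, and mixtures of distinct waveform shapes score
#' higher than a single shape at the same noise level.
#'
#' @param waveforms matrix of cutouts (rows = spikes, 96 columns)
#' @param sample_window sample indices entering the sum (1-based)
#' @return variability (dimensionless, >= 0)
#' @export
compute_variability <- function(waveforms, sample_window = 9:59) {
  stopifnot(is.matrix(waveforms), ncol(waveforms) == 96L)
  if (nrow(waveforms) < 2L) stop("need at least 2 waveforms")
  mean_raw <- colMeans(waveforms)
  amp <- max(abs(mean_raw))
  if (amp == 0) stop("zero-amplitude mean waveform")
  W <- waveforms / amp
  mean_ap <- colMeans(W)
  sd_ap <- apply(W, 2, stats::sd)
  num <- abs(sum(sd_ap[sample_window] * mean_ap[sample_window]) /
               length(sample_window))
  num / max(abs(mean_ap))
}

#' Screen an electrode for single-neuron activity
#'
#' An electrode is treated as recording from a single neuron when (a) it
#' fired at least `min_spikes` times during the first hour of baseline,
#' (b) none of its inter-spike intervals violates the 1-ms refractory
#' period, and (c) the waveform variability of those first-hour cutouts
#' is below `variability_max`.
#'
#' @param recording an `mea_recording` with waveform cutouts attached
#' @param electrode electrode id
#' @param min_spikes minimum spike count in baseline hour 1
#' @param refractory_ms refractory period (ms)
#' @param variability_max variability threshold
#' @param exclude_stim drop spikes inside the hourly stimulation segment
#'   (only meaningful when the recording has a stimulation schedule)
#' @return list of class `variability_result`: `electrode`,
#'   `n_spikes_baseline_h1`, `refractory_violations`, `variability`,
#'   `is_single_neuron`
#' @export
single_neuron_screen <- function(recording, electrode, min_spikes = 100L,
                                 refractory_ms = 1, variability_max = 1,
                                 exclude_stim = TRUE) {
  if (is.null(recording$waveforms))
    stop("recording carries no waveform cutouts")
  sp <- recording$spikes
  sel <- sp$electrode == electrode & sp$time_s < 3600
  if (exclude_stim && !is.null(recording$schedule))
    sel <- sel & !in_stim_segment(sp$time_s / 3600)
  idx <- which(sel)
  tt <- sp$time_s[idx]
  n <- length(idx)
  viol <- if (n >= 2L) sum(diff(tt) < refractory_ms / 1000) else 0L
  variability <- if (n >= 2L)
    compute_variability(recording$waveforms[idx, , drop = FALSE])
  else NA_real_
  structure(list(
    electrode = electrode,
    n_spikes_baseline_h1 = n,
    refractory_violations = viol,
    variability = variability,
    is_single_neuron = n >= min_spikes && viol == 0L &&
      !is.na(variability) && variability < variability_max
  ), class = "variability_result")
}

#' Track the hourly mean action-potential shape of an electrode
#'
#' For every clock hour with at least `min_spikes_hour` cutouts
#' (stimulation-segment spikes excluded when a schedule is present), the
#' mean waveform, its amplitude (max absolute value) and the mean Pearson
#' correlation with the mean waveforms of all preceding non-missing hours
#' are computed. The shape counts as constant while that correlation
#' stays above `cor_min` *and* the amplitude stays at or above
#' `amp_frac_min` of its baseline value (the mean amplitude over
#' baseline-phase hours). Hours with too few spikes are marked missing
#' and do not break constancy by themselves.
#'
#' @param recording an `mea_recording` with waveforms
#' @param electrode electrode id
#' @param min_spikes_hour minimum cutouts per hourly average
#' @param cor_min correlation threshold for constancy
#' @param amp_frac_min amplitude threshold as a fraction of baseline
#' @param exclude_stim drop spikes inside the stimulation segment
#' @return object of class `waveform_track`: data.frame `hours` (`hour`,
#'   `n_spikes`, `missing`, `amplitude`, `r_mean`, `constant`), matrix
#'   `mean_ap` (one row per non-missing hour), `baseline_amplitude`,
#'   `first_violation_h`, `constant_until_h`
#' @export
track_shape <- function(recording, electrode, min_spikes_hour = 5L,
                        cor_min = 0.9, amp_frac_min = 0.8,
                        exclude_stim = TRUE) {
  if (is.null(recording$waveforms))
    stop("recording carries no waveform cutouts")
  sp <- recording$spikes
  n_hours <- floor(recording$duration_h + 1e-9)
  if (n_hours < 1L) stop("recording shorter than one hour")
  sel_e <- sp$electrode == electrode
  if (exclude_stim && !is.null(recording$schedule))
    sel_e <- sel_e & !in_stim_segment(sp$time_s / 3600)
  hour_of <- floor(sp$time_s / 3600)

  hours <- data.frame(hour = seq_len(n_hours) - 1L)
  hours$n_spikes <- vapply(hours$hour, function(h)
    sum(sel_e & hour_of == h), integer(1))
  hours$missing <- hours$n_spikes < min_spikes_hour
  mean_ap <- matrix(NA_real_, n_hours, 96L)
  for (h in which(!hours$missing)) {
    idx <- which(sel_e & hour_of == hours$hour[h])
    mean_ap[h, ] <- colMeans(recording$waveforms[idx, , drop = FALSE])
  }
  hours$amplitude <- apply(mean_ap, 1, function(w)
    if (all(is.na(w))) NA_real_ else max(abs(w)))

  present <- which(!hours$missing)
  if (length(present) < 2L)
    stop("fewer than 2 hours with enough spikes to track the shape")
  hours$r_mean <- NA_real_
  for (k in seq_along(present)[-1]) {
    h <- present[k]
    prev <- present[seq_len(k - 1L)]
    hours$r_mean[h] <- mean(vapply(prev, function(g)
      stats::cor(mean_ap[h, ], mean_ap[g, ]), numeric(1)))
  }

  base_hours <- present[phase_at(recording$timeline,
                                 hours$hour[present] + 0.5) == "baseline"]
  baseline_amplitude <- if (length(base_hours))
    mean(hours$amplitude[base_hours]) else hours$amplitude[present[1]]

  hours$constant <- NA
  hours$constant[present] <-
    (is.na(hours$r_mean[present]) | hours$r_mean[present] > cor_min) &
    hours$amplitude[present] >= amp_frac_min * baseline_amplitude

  viol <- present[which(!hours$constant[present])]
  first_violation_h <- if (length(viol)) hours$hour[viol[1]] else NA_real_
  constant_until_h <- if (is.na(first_violation_h))
    hours$hour[present[length(present)]]
  else if (length(before <- present[hours$hour[present] < first_violation_h]))
    hours$hour[before[length(before)]]
  else NA_real_

  structure(list(
    electrode = electrode, hours = hours, mean_ap = mean_ap,
    baseline_amplitude = baseline_amplitude,
    first_violation_h = first_violation_h,
    constant_until_h = constant_until_h
  ), class = "waveform_track")
}

#' Assign the fate of a single-neuron electrode
#'
#' A unit is inactive from hour h when it fires no spikes from h to the
#' end of the recording. Fates: `active_throughout` (spikes up to the
#' final hour), `inactive_after_change` (a shape-constancy violation
#' precedes the silence) or `inactive_no_change`.
#'
#' @param track a [track_shape()] result
#' @param recording_end_h recording length in whole hours (defaults to
#'   the span of the track)
#' @return list: `fate`, `inactive_from_h` (NA when active throughout),
#'   `first_violation_h`
#' @export
assign_fate <- function(track, recording_end_h = nrow(track$hours)) {
  counts <- track$hours$n_spikes[track$hours$hour < recording_end_h]
  nonzero <- which(counts > 0)
  inactive_from <- if (length(nonzero) && max(nonzero) < length(counts))
    track$hours$hour[max(nonzero) + 1L]
  else if (!length(nonzero)) 0
  else NA_real_
  fate <- if (is.na(inactive_from)) "active_throughout"
  else if (!is.na(track$first_violation_h) &&
           track$first_violation_h <= inactive_from) "inactive_after_change"
  else "inactive_no_change"
  list(fate = fate, inactive_from_h = inactive_from,
       first_violation_h = track$first_violation_h)
}
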