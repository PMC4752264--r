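#' Peristimulus time histogram of the array-wide response
#'
#' Counts spikes on all electrodes in latency bins after each pulse of a
#' stimulation electrode and averages over pulses. Latencies inside the
#' artefact blanking window (0-2 ms by default) are excluded on all
#' electrodes, since residual stimulation artefacts are not analysable
#' as spikes.
#'
#' @param recording an `mea_recording`
#' @param pulse_times pulse times (s) of one stimulation electrode
#' @param t_max_ms PSTH latency span (ms); must cover at least 150 ms
#'   for [compute_asyn()]
#' @param bin_ms latency bin width (ms)
#' @param blank_ms artefact blanking window after the pulse (ms)
#' @return object of class `psth`: `counts` (mean spikes per pulse per
#'   bin), `bin_ms`, `t_max_ms`, `n_pulses`
#' @export
build_psth <- function(recording, pulse_times, t_max_ms = 200, bin_ms = 1,
                       blank_ms = 2) {
  if (length(pulse_times) == 0L) stop("no pulses")
  t_end <- recording$duration_h * 3600
  if (any(pulse_times < 0 | pulse_times > t_end))
    stop("pulses outside the recording")
  n_bins <- as.integer(round(t_max_ms / bin_ms))
  tt <- sort(recording$spikes$time_s)
  acc <- numeric(n_bins)
  t_max_s <- t_max_ms / 1000
  for (tp in pulse_times) {
    lo <- findInterval(tp, tt) + 1L
    hi <- findInterval(tp + t_max_s, tt)
    if (hi < lo) next
    lat_ms <- (tt[lo:hi] - tp) * 1000
    lat_ms <- lat_ms[lat_ms >= blank_ms & lat_ms < t_max_ms]
    if (length(lat_ms))
      acc <- acc + tabulate(floor(lat_ms / bin_ms) + 1L, nbins = n_bins)
  }
  structure(list(counts = acc / length(pulse_times), bin_ms = bin_ms,
                 t_max_ms = t_max_ms, n_pulses = length(pulse_times)),
            class = "psth")
}

#' Synaptically mediated response area (A_syn)
#'
#' Sum of the per-pulse-averaged PSTH over the half-open latency window
#' [15, 150) ms, i.e. the expected number of synaptically mediated spikes
#' per pulse. The early (< 15 ms) direct phase is excluded because it
#' mixes directly triggered and synaptically mediated action potentials.
#'
#' @param psth a [build_psth()] result
#' @param window_ms half-open latency window (ms)
#' @return A_syn (spikes per pulse, >= 0)
#' @export
compute_asyn <- function(psth, window_ms = c(15, 150)) {
  if (psth$t_max_ms < window_ms[2])
    stop("PSTH covers less than ", window_ms[2], " ms")
  edges <- (seq_along(psth$counts) - 1L) * psth$bin_ms
  sum(psth$counts[edges >= window_ms[1] & edges < window_ms[2]])
}

#' A_syn per stimulation electrode per hourly block
#'
#' @param recording an `mea_recording` carrying a stimulation schedule
#'   (or pass one explicitly)
#' @param schedule a [stimulation_schedule()]
#' @inheritParams build_psth
#' @return data.frame: `stim_electrode`, `hour`, `phase`, `n_pulses`,
#'   `asyn`
#' @export
asyn_series <- function(recording, schedule = recording$schedule,
                        t_max_ms = 200, bin_ms = 1, blank_ms = 2) {
  if (is.null(schedule)) stop("no stimulation schedule")
  out <- list(); k <- 0L
  for (e in sort(unique(schedule$electrode))) {
    for (h in sort(unique(schedule$hour))) {
      pulses <- schedule$time_s[schedule$electrode == e & schedule$hour == h]
      if (!length(pulses)) next
      ps <- build_psth(recording, pulses, t_max_ms, bin_ms, blank_ms)
      k <- k + 1L
      out[[k]] <- data.frame(
        stim_electrode = e, hour = h,
        phase = if (!is.null(recording$timeline))
          phase_at(recording$timeline, h + 0.5) else NA_character_,
        n_pulses = length(pulses),
        asyn = compute_asyn(ps))
    }
  }
  do.call(rbind, out)
}

#' Normalize an A_syn series to its baseline value
#'
#' Each stimulation electrode's A_syn is divided by its mean over
#' baseline-phase blocks. Electrodes whose baseline A_syn falls below
#' `min_baseline` spikes are flagged excluded: their normalization is
#' unstable and they are dropped from averaged series.
#'
#' @param series from [asyn_series()] (needs `stim_electrode`, `phase`,
#'   `asyn`)
#' @param min_baseline minimum baseline A_syn (spikes per pulse)
#' @return the series with `asyn_baseline`, `asyn_norm` and `excluded`
#'   columns added
#' @export
normalize_asyn <- function(series, min_baseline = 6) {
  base <- tapply(series$asyn[series$phase == "baseline"],
                 series$stim_electrode[series$phase == "baseline"], mean)
  series$asyn_baseline <- as.numeric(base[as.character(series$stim_electrode)])
  series$excluded <- is.na(series$asyn_baseline) |
    series$asyn_baseline < min_baseline
  series$asyn_norm <- ifelse(series$excluded, NA_real_,
                             series$asyn / series$asyn_baseline)
  series
}
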