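#' Array-wide firing rate on the experiment timeline
#'
#' Total spike count over all electrodes in 30-min bins aligned to
#' experiment start, normalized to the mean count over *complete*
#' baseline bins. A trailing partial bin is reported but excluded from
#' all normalization statistics.
#'
#' @param recording an `mea_recording` (or any list with `spikes` and a
#'   `timeline`)
#' @param bin_min bin width (minutes)
#' @return data.frame of class `awfr_series`: `bin_start_h`, `bin_end_h`,
#'   `phase`, `complete`, `count`, `normalized`; attribute
#'   `baseline_mean` (NA, with `normalization_failed = TRUE`, when the
#'   baseline carries no activity or no complete bin)
#' @export
compute_awfr <- function(recording, bin_min = 30) {
  T_h <- recording$duration_h
  bin_h <- bin_min / 60
  if (T_h < bin_h) stop("recording spans less than one bin")
  n_bin <- ceiling(T_h / bin_h - 1e-9)
  t_h <- recording$spikes$time_s / 3600
  idx <- pmin(floor(t_h / bin_h) + 1L, n_bin)
  count <- tabulate(idx, nbins = n_bin)
  start_h <- (seq_len(n_bin) - 1L) * bin_h
  end_h <- pmin(start_h + bin_h, T_h)
  complete <- (start_h + bin_h) <= T_h + 1e-9
  phase <- phase_at(recording$timeline, start_h + bin_h / 2)
  base <- complete & phase == "baseline"
  baseline_mean <- if (any(base) && sum(count[base]) > 0)
    mean(count[base]) else NA_real_
  out <- data.frame(bin_start_h = start_h, bin_end_h = end_h,
                    phase = phase, complete = complete, count = count,
                    normalized = count / baseline_mean)
  attr(out, "baseline_mean") <- baseline_mean
  attr(out, "normalization_failed") <- is.na(baseline_mean)
  if (is.na(baseline_mean))
    warning("no activity in complete baseline bins; normalization undefined")
  class(out) <- c("awfr_series", "data.frame")
  out
}

#' Per-electrode firing rates by phase
#'
#' @param recording an `mea_recording`
#' @return data.frame: `electrode`, `phase`, `rate` (spikes/s)
#' @export
electrode_phase_rates <- function(recording) {
  tl <- recording$timeline
  sp <- recording$spikes
  out <- list()
  for (r in seq_len(nrow(tl))) {
    dur <- (min(tl$end_h[r], recording$duration_h) - tl$start_h[r]) * 3600
    if (dur <= 0) next
    t_h <- sp$time_s / 3600
    sel <- t_h >= tl$start_h[r] & t_h < tl$end_h[r]
    cnt <- tabulate(sp$electrode[sel], nbins = recording$n_electrodes)
    out[[r]] <- data.frame(electrode = seq_len(recording$n_electrodes),
                           phase = tl$phase[r], rate = cnt / dur)
  }
  do.call(rbind, out)
}

#' Flag focally hyperactive electrodes during hypoxia
#'
#' During hypoxia a handful of electrodes (1-3) can pick up strongly
#' increased, asynchronous firing from disinhibited intrinsically active
#' neurons while the rest of the array is suppressed; these outliers
#' dominate the array-wide firing rate and are removed before averaging.
#' The deterministic rule: an electrode is focal if its hypoxia-phase
#' mean rate exceeds its baseline mean rate while the median normalized
#' rate of the remaining electrodes is below `array_median_max`. If the
#' array as a whole is not suppressed, nothing is flagged (global
#' elevation is not focal).
#'
#' @param recording an `mea_recording`
#' @param array_median_max suppression criterion on the median normalized
#'   rate of non-flagged electrodes (default 0.75)
#' @param min_baseline_rate electrodes quieter than this at baseline
#'   (spikes/s) are ignored by the rule
#' @return integer vector of flagged electrode ids (possibly empty), with
#'   the rule parameters attached as attributes
#' @export
flag_focal_electrodes <- function(recording, array_median_max = 0.75,
                                  min_baseline_rate = 0.01) {
  rates <- electrode_phase_rates(recording)
  base <- rates[rates$phase == "baseline", ]
  hyp <- rates[rates$phase == "hypoxia", ]
  if (nrow(hyp) == 0L) return(integer(0))
  stopifnot(identical(base$electrode, hyp$electrode))
  up <- hyp$rate > base$rate & base$rate >= min_baseline_rate
  # electrodes with no baseline activity that light up under hypoxia are
  # focal candidates too (tonic units can be near-silent at baseline)
  up <- up | (base$rate < min_baseline_rate & hyp$rate > 10 * min_baseline_rate)
  norm <- ifelse(base$rate > 0, hyp$rate / base$rate, Inf)
  rest <- norm[!up & base$rate > 0]
  flagged <- if (length(rest) && stats::median(rest) < array_median_max)
    base$electrode[up] else integer(0)
  attr(flagged, "array_median_max") <- array_median_max
  attr(flagged, "median_rest_normalized") <-
    if (length(rest)) stats::median(rest) else NA_real_
  flagged
}
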