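#' Robust noise-level estimate for one electrode trace
#'
#' Median absolute deviation scaled by 1/0.6745 (the Gaussian consistency
#' factor), computed over consecutive 10-s windows and summarised by the
#' median across windows. MAD is insensitive to the rare large-amplitude
#' spike samples riding on the noise floor, which is what a plain SD
#' estimate would be biased by.
#'
#' @param trace numeric voltage trace (uV)
#' @param fs sample rate (Hz)
#' @param window_s window length (s); the trace must cover at least 1 s
#' @return list of class `noise_estimate`: `sigma` (uV), `window_s`,
#'   `n_windows`
#' @export
estimate_noise <- function(trace, fs = 16000, window_s = 10) {
  if (length(trace) == 0) stop("empty trace")
  if (length(trace) < fs) stop("trace shorter than 1 s")
  wlen <- window_s * fs
  n_win <- max(1L, floor(length(trace) / wlen))
  sig <- vapply(seq_len(n_win), function(w) {
    seg <- trace[((w - 1L) * wlen + 1L):min(length(trace), w * wlen)]
    stats::mad(seg, center = stats::median(seg), constant = 1) / 0.6745
  }, numeric(1))
  structure(list(sigma = stats::median(sig), window_s = window_s,
                 n_windows = n_win), class = "noise_estimate")
}

#' Threshold spike detection with waveform cutouts
#'
#' A spike opens whenever the absolute signal exceeds
#' `threshold_factor * sigma` (default 5.5 x the estimated noise level).
#' The peak is the local maximum of the absolute signal within the
#' supra-threshold episode; a 96-sample cutout is taken from 2 ms before
#' the peak (sample 33 of the cutout) to 4 ms after. After a peak, a
#' 1-ms dead time must elapse before a new crossing can open an event;
#' crossings inside the dead time are absorbed into the previous event.
#' Peaks whose cutout would run off either end of the trace are dropped.
#'
#' @param trace numeric voltage trace
#' @param noise a [estimate_noise()] result, or a positive number taken as
#'   sigma directly
#' @param fs sample rate (Hz)
#' @param threshold_factor detection threshold in units of sigma
#' @param dead_time_ms dead time after a peak (ms)
#' @param electrode optional electrode id stored with the events
#' @return list of class `spike_events`: data.frame `events`
#'   (`time_s`, `electrode`, `peak_sample`) and matrix `waveforms`
#'   (one 96-sample row per event, peak at column 33)
#' @export
detect_spikes <- function(trace, noise, fs = 16000, threshold_factor = 5.5,
                          dead_time_ms = 1, electrode = NA_integer_) {
  sigma <- if (inherits(noise, "noise_estimate")) noise$sigma else noise
  if (!is.numeric(sigma) || sigma <= 0)
    stop("noise sigma must be positive; degenerate (constant?) trace")
  if (length(trace) < 96L) stop("trace shorter than one cutout")
  thr <- threshold_factor * sigma
  above <- abs(trace) > thr
  if (!any(above)) {
    return(structure(list(
      events = data.frame(time_s = numeric(0), electrode = integer(0),
                          peak_sample = integer(0)),
      waveforms = matrix(numeric(0), 0, 96), sigma = sigma,
      threshold = thr), class = "spike_events"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep_start <- starts[r$values]
  ep_end <- ends[r$values]
  dead <- round(dead_time_ms / 1000 * fs)
  peaks <- integer(0)
  for (i in seq_along(ep_start)) {
    seg <- ep_start[i]:ep_end[i]
    pk <- seg[which.max(abs(trace[seg]))]
    if (length(peaks) && ep_start[i] - peaks[length(peaks)] <= dead) {
      # crossing inside the dead time: absorb into the previous event,
      # keeping whichever extremum is larger
      if (abs(trace[pk]) > abs(trace[peaks[length(peaks)]]))
        peaks[length(peaks)] <- pk
    } else {
      peaks <- c(peaks, pk)
    }
  }
  ok <- peaks - 32L >= 1L & peaks + 63L <= length(trace)
  peaks <- peaks[ok]
  W <- if (length(peaks)) {
    t(vapply(peaks, function(p) trace[(p - 32L):(p + 63L)], numeric(96)))
  } else matrix(numeric(0), 0, 96)
  structure(list(
    events = data.frame(time_s = (peaks - 1L) / fs,
                        electrode = rep(electrode, length(peaks)),
                        peak_sample = peaks),
    waveforms = W, sigma = sigma, threshold = thr
  ), class = "spike_events")
}

#' Detect spikes on a set of raw traces
#'
#' Convenience wrapper running [estimate_noise()] and [detect_spikes()]
#' per electrode and assembling the package-wide spike-table layout.
#'
#' @param traces named list of per-electrode traces (as returned by
#'   [render_raw_traces()])
#' @param fs sample rate (Hz)
#' @param threshold_factor detection threshold in units of sigma
#' @return list: `spikes` data.frame (`time_s`, `electrode`),
#'   `waveforms` matrix, `noise` per-electrode sigma vector
#' @export
detect_array <- function(traces, fs = attr(traces, "fs") %||% 16000,
                         threshold_factor = 5.5) {
  res <- lapply(names(traces), function(nm) {
    ns <- estimate_noise(traces[[nm]], fs = fs)
    detect_spikes(traces[[nm]], ns, fs = fs,
                  threshold_factor = threshold_factor,
                  electrode = as.integer(nm))
  })
  ev <- do.call(rbind, lapply(res, function(d) d$events))
  W <- do.call(rbind, lapply(res, function(d) d$waveforms))
  ord <- order(ev$time_s, ev$electrode)
  list(spikes = ev[ord, c("time_s", "electrode")],
       waveforms = W[ord, , drop = FALSE],
       noise = vapply(res, function(d) d$sigma, numeric(1)))
}

#' Screen detected events for artefacts
#'
#' Two documented rules stand in for full offline artefact classification:
#' (a) coincidence artefacts - events occurring within `coincidence_ms`
#' of each other on more than `k_electrodes` electrodes with
#' near-identical waveforms (mean correlation with the group mean above
#' `cor_min`) are rejected as pickup of a common electrical transient;
#' (b) saturation - cutouts with `sat_run` or more consecutive samples
#' pinned at the cutout's absolute maximum are rejected as clipped.
#'
#' @param events data.frame with `time_s` and `electrode`
#' @param waveforms matrix of cutouts, rows aligned with `events`
#' @param k_electrodes coincidence-size threshold (strictly more than
#'   this many electrodes at once triggers rejection)
#' @param coincidence_ms coincidence window (ms)
#' @param cor_min waveform-similarity threshold for coincidence rejection
#' @param sat_run run length of pinned samples that flags clipping
#' @return list with `kept` and `rejected` (row indices into `events`)
#'   plus the filtered `events`/`waveforms`
#' @export
screen_artefacts <- function(events, waveforms, k_electrodes = 6L,
                             coincidence_ms = 0.2, cor_min = 0.95,
                             sat_run = 4L) {
  n <- nrow(events)
  if (n == 0L)
    return(list(kept = integer(0), rejected = integer(0),
                events = events, waveforms = waveforms))
  reject <- logical(n)

  # (b) clipped/saturated cutouts
  for (i in seq_len(n)) {
    w <- waveforms[i, ]
    m <- max(abs(w))
    if (m == 0) next
    runs <- rle(abs(w) >= m * 0.999)
    if (any(runs$values & runs$lengths >= sat_run)) reject[i] <- TRUE
  }

  # (a) coincidence groups with near-identical waveforms
  ord <- order(events$time_s)
  ts <- events$time_s[ord]
  grp <- cumsum(c(TRUE, diff(ts) > coincidence_ms / 1000))
  for (g in split(ord, grp)) {
    if (length(unique(events$electrode[g])) <= k_electrodes) next
    Wg <- waveforms[g, , drop = FALSE]
    ref <- colMeans(Wg)
    if (stats::sd(ref) == 0) next
    cc <- apply(Wg, 1, function(w)
      if (stats::sd(w) == 0) 0 else stats::cor(w, ref))
    if (mean(cc) > cor_min) reject[g] <- TRUE
  }

  kept <- which(!reject)
  list(kept = kept, rejected = which(reject),
       events = events[kept, , drop = FALSE],
       waveforms = waveforms[kept, , drop = FALSE])
}
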