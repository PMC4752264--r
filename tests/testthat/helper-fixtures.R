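# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; nothing is read from disk.

# Assemble a bare recording from a spike data.frame (fixture path that
# bypasses the generator).
make_recording <- function(spikes, n_electrodes = 60L, duration_h,
                           timeline = NULL, waveforms = NULL,
                           schedule = NULL) {
  if (is.null(spikes$unit)) spikes$unit <- rep(NA_integer_, nrow(spikes))
  if (is.null(spikes$evoked)) spikes$evoked <- rep(FALSE, nrow(spikes))
  rec <- penumbra:::new_recording(spikes, ground_truth = NULL,
                                  protocol = NULL, duration_h = duration_h,
                                  schedule = schedule, waveforms = waveforms)
  rec$n_electrodes <- as.integer(n_electrodes)
  rec$timeline <- timeline
  rec
}

make_block <- function(spikes, active, n_electrodes,
                       index = 1L, phase = "baseline") {
  structure(list(index = index,
                 spikes = spikes[order(spikes$time_s), , drop = FALSE],
                 active = active,
                 t_start_s = min(spikes$time_s), t_end_s = max(spikes$time_s),
                 mid_h = mean(range(spikes$time_s)) / 3600, phase = phase,
                 n_electrodes = as.integer(n_electrodes)),
            class = "data_block")
}

# O(n^2) brute-force CFP oracle: literal transliteration of the
# definition, one explicit pass per (conditioning spike, latency bin).
brute_cfp <- function(spikes, i, j, tau_bin_ms = 0.5, tau_max_ms = 500) {
  ti <- spikes$time_s[spikes$electrode == i]
  tj <- spikes$time_s[spikes$electrode == j]
  nb <- round(tau_max_ms / tau_bin_ms)
  p <- numeric(nb)
  if (!length(ti)) return(p)
  for (b in seq_len(nb)) {
    lo <- (b - 1) * tau_bin_ms / 1000
    hi <- b * tau_bin_ms / 1000
    cnt <- 0L
    for (t0 in ti) cnt <- cnt + any(tj > t0 + lo & tj <= t0 + hi)
    p[b] <- cnt / length(ti)
  }
  p
}

# Sample-by-sample detection oracle: contiguous supra-threshold episodes,
# peak = argmax |x| within the episode, episodes starting within the dead
# time of the previous event's peak are absorbed (larger extremum wins).
brute_detect <- function(trace, sigma, fs = 16000, threshold_factor = 5.5,
                         dead_time_ms = 1) {
  thr <- threshold_factor * sigma
  dead <- round(dead_time_ms / 1000 * fs)
  peaks <- integer(0)
  n <- length(trace)
  s <- 1L
  while (s <= n) {
    if (abs(trace[s]) > thr) {
      e <- s
      while (e < n && abs(trace[e + 1L]) > thr) e <- e + 1L
      seg <- s:e
      pk <- seg[which.max(abs(trace[seg]))]
      if (length(peaks) && s - peaks[length(peaks)] <= dead) {
        if (abs(trace[pk]) > abs(trace[peaks[length(peaks)]]))
          peaks[length(peaks)] <- pk
      } else peaks <- c(peaks, pk)
      s <- e + 1L
    } else s <- s + 1L
  }
  peaks[peaks - 32L >= 1L & peaks + 63L <= n]
}

# Direct transliteration of the waveform-variability formula, kept
# separate from the implementation under test.
brute_variability <- function(W, window = 9:59) {
  m_raw <- colMeans(W)
  Wn <- W / max(abs(m_raw))
  m <- colMeans(Wn)
  s <- apply(Wn, 2, sd)
  abs(sum(s[window] * m[window]) / length(window)) / max(abs(m))
}

# Gaussian noise truncated at +/- bound_sd standard deviations (resample
# until inside the bound): bounded noise for exact zero-false-positive
# detection fixtures.
truncated_noise <- function(n, sd = 1, bound_sd = 5) {
  x <- rnorm(n, 0, sd)
  out <- abs(x) > bound_sd * sd
  while (any(out)) {
    x[out] <- rnorm(sum(out), 0, sd)
    out <- abs(x) > bound_sd * sd
  }
  x
}

normoxic_protocol <- function(hours = 1)
  hypoxia_protocol(phase_timeline(hours, 0, 0))

# Disjoint planted edges (a perfect matching) so that neither chains nor
# shared sources create indirect CFP structure.
matched_edges <- function(n_units, n_edges, strength, delay_ms) {
  perm <- sample(n_units)
  data.frame(from = perm[seq_len(n_edges)],
             to = perm[n_edges + seq_len(n_edges)],
             strength = strength, delay_ms = delay_ms)
}
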