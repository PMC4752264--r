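#' Ground-truth network for the synthetic MEA generator
#'
#' Defines the units behind a simulated culture: one unit per electrode by
#' default (60 electrodes), ~80% excitatory / ~20% inhibitory, plus
#' optional intrinsically active (tonic) units. Excitatory units fire as
#' near-Poisson processes; inhibitory units fire in rare intense bursts on
#' a nearly silent background, which drives the standard-deviation-to-mean
#' ratio of their 6-s spike counts far above the excitatory range.
#' Directed excitatory coupling is a per-spike follow probability: a spike
#' of unit i triggers a spike of unit j with probability
#' `adjacency[i, j] * efficacy(t)` at lag `delay_ms[i, j]` (plus small
#' jitter). That makes planted edges directly visible as conditional
#' firing probability peaks.
#'
#' @param n_units number of units (= electrodes by default)
#' @param n_electrodes number of array electrodes (default 60, or
#'   `n_units` if larger)
#' @param frac_inhibitory fraction of inhibitory units
#' @param n_tonic number of intrinsically active (tonic) units; these are
#'   drawn from the excitatory pool, fire regularly and are *not* scaled
#'   down by the hypoxic rate multiplier (emulating disinhibited
#'   intrinsically active neurons)
#' @param base_rate_range uniform range of excitatory baseline rates
#'   (spikes/s)
#' @param burst_rate_per_h inhibitory burst onsets per hour
#' @param burst_size mean spikes per inhibitory burst
#' @param burst_duration_s inhibitory burst duration (s)
#' @param quiet_rate inhibitory between-burst rate (spikes/s)
#' @param tonic_rate firing rate of tonic units (spikes/s)
#' @param n_edges number of directed excitatory couplings (default
#'   `2 * n_units`); sources are excitatory units
#' @param strength_range uniform range of per-spike follow probabilities
#' @param delay_range_ms uniform range of synaptic delays (ms)
#' @param edges optional explicit edge data.frame (`from`, `to`,
#'   `strength`, `delay_ms`) overriding random wiring
#' @param amplitude_range uniform range of template peak amplitudes (uV)
#' @param seed optional integer seed for the wiring draw
#' @return object of class `network_ground_truth`
#' @export
network_ground_truth <- function(n_units = 60L,
                                 n_electrodes = max(60L, n_units),
                                 frac_inhibitory = 0.2,
                                 n_tonic = 0L,
                                 base_rate_range = c(0.5, 2),
                                 burst_rate_per_h = 1.0,
                                 burst_size = 150,
                                 burst_duration_s = 1,
                                 quiet_rate = 0.005,
                                 tonic_rate = 4,
                                 n_edges = 2L * n_units,
                                 strength_range = c(0.15, 0.35),
                                 delay_range_ms = c(2, 10),
                                 edges = NULL,
                                 amplitude_range = c(40, 80),
                                 seed = NULL) {
  stopifnot(n_units >= 1, n_units <= n_electrodes,
            frac_inhibitory >= 0, frac_inhibitory <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_inh <- round(n_units * frac_inhibitory)
  cls <- rep("excitatory", n_units)
  if (n_inh > 0) cls[sample.int(n_units, n_inh)] <- "inhibitory"
  if (n_tonic > 0) {
    exc_idx <- which(cls == "excitatory")
    stopifnot(n_tonic <= length(exc_idx))
    cls[sample(exc_idx, n_tonic)] <- "intrinsic"
  }
  base_rate <- stats::runif(n_units, base_rate_range[1], base_rate_range[2])
  base_rate[cls == "intrinsic"] <- tonic_rate

  adjacency <- matrix(0, n_units, n_units)
  delay_ms <- matrix(NA_real_, n_units, n_units)
  if (is.null(edges)) {
    src_pool <- which(cls == "excitatory")
    if (length(src_pool) >= 1 && n_edges > 0 && n_units >= 2) {
      from <- sample(src_pool, n_edges, replace = TRUE)
      to <- vapply(from, function(f)
        sample(setdiff(seq_len(n_units), f), 1L), integer(1))
      edges <- data.frame(
        from = from, to = to,
        strength = stats::runif(n_edges, strength_range[1], strength_range[2]),
        delay_ms = stats::runif(n_edges, delay_range_ms[1], delay_range_ms[2])
      )
      edges <- edges[!duplicated(edges[c("from", "to")]), ]
    } else {
      edges <- data.frame(from = integer(0), to = integer(0),
                          strength = numeric(0), delay_ms = numeric(0))
    }
  } else {
    edges <- as.data.frame(edges)
    stopifnot(all(c("from", "to", "strength", "delay_ms") %in% names(edges)),
              all(edges$strength >= 0), all(edges$delay_ms > 0),
              all(edges$from != edges$to))
  }
  if (nrow(edges)) {
    adjacency[cbind(edges$from, edges$to)] <- edges$strength
    delay_ms[cbind(edges$from, edges$to)] <- edges$delay_ms
  }

  amp <- stats::runif(n_units, amplitude_range[1], amplitude_range[2])
  templates <- t(vapply(seq_len(n_units), function(u)
    ap_template(amplitude = amp[u],
                width = stats::runif(1, 0.9, 1.15),
                rebound = stats::runif(1, 0.25, 0.45)),
    numeric(96)))

  structure(list(
    n_units = as.integer(n_units),
    n_electrodes = as.integer(n_electrodes),
    unit_electrode = seq_len(n_units),
    unit_class = cls,
    base_rate = base_rate,
    burst_rate_per_h = burst_rate_per_h,
    burst_size = burst_size,
    burst_duration_s = burst_duration_s,
    quiet_rate = quiet_rate,
    edges = edges,
    adjacency = adjacency,
    delay_ms = delay_ms,
    template = templates,
    template_amplitude = amp
  ), class = "network_ground_truth")
}

#' @export
print.network_ground_truth <- function(x, ...) {
  cat("Synthetic MEA ground truth:", x$n_units, "units on",
      x$n_electrodes, "electrodes\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$unit_class)),
                                  table(x$unit_class)), collapse = ", "), "\n")
  cat("  coupled edges:", nrow(x$edges),
      sprintf("(strengths %.2f-%.2f)",
              suppressWarnings(min(x$edges$strength)),
              suppressWarnings(max(x$edges$strength))), "\n")
  invisible(x)
}
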