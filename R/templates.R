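#' Build an extracellular action-potential waveform template
#'
#' Returns a 96-sample cutout (6 ms at 16 kHz) with the canonical biphasic
#' extracellular shape: a sharp negative deflection with its extremum at
#' sample 33 (2 ms into the cutout) followed by a slower positive rebound.
#' Amplitude is the peak absolute value in signal units (microvolts by
#' convention throughout the package).
#'
#' @param amplitude peak absolute value of the template (uV)
#' @param width widening factor; 1 gives the canonical width, larger values
#'   stretch the waveform around the peak (used to emulate the progressive
#'   widening seen when membrane integrity degrades)
#' @param rebound relative amplitude of the positive after-wave (0..1)
#' @param n_samples cutout length (96 = 6 ms at 16 kHz)
#' @param peak_sample index of the peak within the cutout (33 = 2 ms)
#' @return numeric vector of length `n_samples`
#' @export
ap_template <- function(amplitude = 60, width = 1, rebound = 0.35,
                        n_samples = 96L, peak_sample = 33L) {
  stopifnot(amplitude > 0, width > 0)
  s <- (seq_len(n_samples) - peak_sample) / width
  neg <- -exp(-(s / 4)^2)                 # ~0.25 ms half-width trough
  pos <- rebound * exp(-((s - 14) / 11)^2) # rebound ~0.9 ms after the peak
  w <- neg + pos
  w / max(abs(w)) * amplitude
}

#' Morph a waveform template (amplitude decay + widening)
#'
#' Emulates the progressive action-potential deformation preceding
#' silencing: linear amplitude loss and width growth per hour past a
#' per-unit onset. Resamples the template at stretched sample positions
#' (linear interpolation, constant extrapolation at the edges).
#'
#' @param template numeric 96-sample template
#' @param hours_past_onset hours elapsed since deformation onset (<= 0
#'   returns the template unchanged)
#' @param amp_loss_per_h fractional amplitude lost per hour
#' @param width_gain_per_h fractional width gained per hour
#' @param peak_sample peak index (stretch centre)
#' @return morphed template, same length
#' @export
morph_template <- function(template, hours_past_onset,
                           amp_loss_per_h = 0.06, width_gain_per_h = 0.08,
                           peak_sample = 33L) {
  if (is.na(hours_past_onset) || hours_past_onset <= 0) return(template)
  amp <- max(0, 1 - amp_loss_per_h * hours_past_onset)
  stretch <- 1 + width_gain_per_h * hours_past_onset
  n <- length(template)
  pos <- (seq_len(n) - peak_sample) / stretch + peak_sample
  y <- stats::approx(seq_len(n), template, xout = pos, rule = 2)$y
  amp * y
}
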