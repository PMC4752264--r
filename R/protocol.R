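#' Experiment phase timeline
#'
#' The protocol is a normoxic baseline (2 h by default), a hypoxic episode,
#' and a recovery period after return to normoxia. Each clock hour consists
#' of a 10-min stimulation segment followed by 50 min of spontaneous
#' recording.
#'
#' @param baseline_h baseline duration (hours)
#' @param hypoxia_h hypoxic episode duration (hours)
#' @param recovery_h post-hypoxia recording duration (hours)
#' @return object of class `phase_timeline`: data.frame with columns
#'   `phase`, `start_h`, `end_h` plus attributes
#' @export
phase_timeline <- function(baseline_h = 2, hypoxia_h = 6, recovery_h = 3) {
  stopifnot(baseline_h > 0, hypoxia_h >= 0, recovery_h >= 0)
  tl <- data.frame(
    phase = c("baseline", "hypoxia", "recovery"),
    start_h = c(0, baseline_h, baseline_h + hypoxia_h),
    end_h = c(baseline_h, baseline_h + hypoxia_h,
              baseline_h + hypoxia_h + recovery_h),
    stringsAsFactors = FALSE
  )
  tl <- tl[tl$end_h > tl$start_h, ]
  class(tl) <- c("phase_timeline", "data.frame")
  tl
}

#' Phase label at given times
#' @param timeline a [phase_timeline()]
#' @param t_h time(s) in hours from experiment start
#' @return character vector of phase labels ("post" past the timeline end)
#' @export
phase_at <- function(timeline, t_h) {
  out <- rep("post", length(t_h))
  for (r in rev(seq_len(nrow(timeline)))) {
    sel <- t_h >= timeline$start_h[r] & t_h < timeline$end_h[r]
    out[sel] <- timeline$phase[r]
  }
  out[t_h < 0] <- NA_character_
  out
}

total_hours <- function(timeline) max(timeline$end_h)

#' Is a time inside the hourly stimulation segment?
#'
#' Stimulation occupies the first 10 minutes of every clock hour.
#' @param t_h time(s) in hours
#' @param stim_min stimulation segment length (minutes)
#' @return logical vector
#' @export
in_stim_segment <- function(t_h, stim_min = 10) {
  (t_h - floor(t_h)) * 60 < stim_min
}

#' Hypoxia protocol: pO2 dynamics and synaptic/rate multipliers
#'
#' Dissolved-oxygen pressure relaxes exponentially between set-points when
#' the gas mixture is switched: from `pO2_baseline` towards `pO2_hypoxia`
#' with time constant `tau_down` at hypoxia onset, and back with `tau_up`
#' at restoration. Synaptic efficacy and baseline firing-rate multipliers
#' track the instantaneous pO2 linearly between the two set-points, from 1
#' at baseline pO2 down to `efficacy_hypoxia` / `rate_hypoxia` at the
#' hypoxic plateau. Baseline-phase multipliers are identically 1.
#'
#' Optional per-unit `silencing_onset_h` and `morph_onset_h` (hours from
#' experiment start; NA = never) put individual units into terminal
#' failure: firing stops at the silencing onset, and the action-potential
#' shape starts to deform (amplitude loss + widening) at the morph onset.
#'
#' @param timeline a [phase_timeline()]
#' @param pO2_baseline baseline oxygen pressure (mmHg)
#' @param pO2_hypoxia hypoxic plateau (mmHg)
#' @param tau_down,tau_up relaxation time constants (h)
#' @param efficacy_hypoxia coupling-strength multiplier at the hypoxic
#'   plateau (0..1)
#' @param rate_hypoxia baseline-rate multiplier at the hypoxic plateau
#' @param silencing_onset_h,morph_onset_h optional per-unit onset hours
#' @return object of class `hypoxia_protocol`
#' @export
hypoxia_protocol <- function(timeline = phase_timeline(),
                             pO2_baseline = 160, pO2_hypoxia = 23,
                             tau_down = 0.95, tau_up = 0.51,
                             efficacy_hypoxia = 0.5, rate_hypoxia = 0.5,
                             silencing_onset_h = NULL,
                             morph_onset_h = NULL) {
  stopifnot(pO2_baseline > pO2_hypoxia, tau_down > 0, tau_up > 0,
            efficacy_hypoxia >= 0, efficacy_hypoxia <= 1,
            rate_hypoxia >= 0, rate_hypoxia <= 1)
  structure(list(
    timeline = timeline,
    pO2_baseline = pO2_baseline, pO2_hypoxia = pO2_hypoxia,
    tau_down = tau_down, tau_up = tau_up,
    efficacy_hypoxia = efficacy_hypoxia, rate_hypoxia = rate_hypoxia,
    silencing_onset_h = silencing_onset_h,
    morph_onset_h = morph_onset_h
  ), class = "hypoxia_protocol")
}

#' Instantaneous pO2 under a hypoxia protocol
#' @param protocol a [hypoxia_protocol()]
#' @param t_h time(s) in hours
#' @return pO2 in mmHg
#' @export
pO2_at <- function(protocol, t_h) {
  tl <- protocol$timeline
  hyp <- tl[tl$phase == "hypoxia", ]
  p <- rep(protocol$pO2_baseline, length(t_h))
  if (nrow(hyp) == 0) return(p)
  t_on <- hyp$start_h
  t_off <- hyp$end_h
  during <- t_h >= t_on & t_h < t_off
  p[during] <- protocol$pO2_hypoxia +
    (protocol$pO2_baseline - protocol$pO2_hypoxia) *
    exp(-(t_h[during] - t_on) / protocol$tau_down)
  after <- t_h >= t_off
  if (any(after)) {
    p_off <- protocol$pO2_hypoxia +
      (protocol$pO2_baseline - protocol$pO2_hypoxia) *
      exp(-(t_off - t_on) / protocol$tau_down)
    p[after] <- protocol$pO2_baseline +
      (p_off - protocol$pO2_baseline) *
      exp(-(t_h[after] - t_off) / protocol$tau_up)
  }
  p
}

pO2_fraction <- function(protocol, t_h) {
  clamp01((pO2_at(protocol, t_h) - protocol$pO2_hypoxia) /
            (protocol$pO2_baseline - protocol$pO2_hypoxia))
}

#' Coupling-efficacy multiplier at given times
#' @inheritParams pO2_at
#' @return multiplier in [efficacy_hypoxia, 1]
#' @export
efficacy_at <- function(protocol, t_h) {
  protocol$efficacy_hypoxia +
    (1 - protocol$efficacy_hypoxia) * pO2_fraction(protocol, t_h)
}

#' Baseline-rate multiplier at given times
#' @inheritParams pO2_at
#' @return multiplier in [rate_hypoxia, 1]
#' @export
rate_mult_at <- function(protocol, t_h) {
  protocol$rate_hypoxia +
    (1 - protocol$rate_hypoxia) * pO2_fraction(protocol, t_h)
}
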