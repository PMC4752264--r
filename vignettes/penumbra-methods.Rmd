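---
title: "Methods: spike-train analysis of cultured networks under hypoxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train analysis of cultured networks under hypoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penumbra)
```

## The problem

Penumbral tissue around a brain infarct is hypoperfused but initially
viable: synaptic transmission fails first, while neurons stay intact for
many hours. Networks of dissociated cortical neurons cultured on
60-electrode arrays (MEAs) and exposed to controlled hypoxia are a
tractable model of that state. The measurable quantities are spike
trains per electrode: from them one can follow overall activity,
functional connectivity between electrodes, the integrity of individual
action-potential waveforms, and the network's ability to relay
electrical stimulation. `penumbra` implements that analysis battery,
together with a synthetic-recording generator that makes every stage
testable against known ground truth — no laboratory recordings are
required to verify the code.

## The synthetic recording generator

### Spiking model

Units (one per electrode by default) are conditionally Poisson point
processes coupled by a branching rule. Unit $i$ fires a baseline train;
each spike of $i$ independently triggers a spike of unit $j$ with
probability $A_{ij}\,\varepsilon(t)$ at the edge's synaptic delay
(2–10 ms) plus Gaussian jitter (SD 0.1 ms), where $A_{ij} \in [0,1]$ is
the coupling strength and $\varepsilon(t)$ the hypoxic efficacy
multiplier. Triggered spikes trigger in turn, so cascades propagate
until extinction; a 1-ms per-unit refractory period is enforced on the
merged train. This model was chosen over membrane-potential models
because conditional firing probability (CFP) — the connectivity
statistic of the pipeline — is defined directly on spike pairs: a
planted edge of strength $A_{ij}$ appears as a CFP peak of essentially
that height at the edge delay, which makes recovery quantifiable. The
jitter SD is kept small relative to the 0.5-ms CFP bin so a planted
follow probability lands almost entirely in one latency bin.

Classes follow the ~80/20 excitatory/inhibitory split of these
cultures. Excitatory units are near-Poisson with baseline rates of
0.5–2 spikes/s (configurable; parameter-recovery fixtures use
2–5 spikes/s). Inhibitory units fire in rare intense bursts
(~1 burst/h of ~150 spikes in ~1 s) on a nearly silent background
(0.005 spikes/s). That design is deliberate: classification of
excitatory vs. inhibitory units uses the ratio of standard deviation to
mean of spike counts in 6-s bins, and the two firing styles must sit on
opposite sides of the published thresholds (7.21 / 12.47). For a
near-Poisson train with tens of spikes per bin the ratio is
$1/\sqrt{\mu} \ll 7.21$. For a burst process with $k$ occupied bins out
of $N$ the ratio approaches $\sqrt{N/k}$, so the burst rate was set
before any testing such that a 4-h window ($N = 2400$) has $k$ around
4–6, putting the ratio near 20–30 with high probability. With shorter
windows the inhibitory ratio is noisier; the package's classification
fixtures therefore use a 4-h normoxic baseline (≥ 600 bins is the
stated validity floor).

Optional *intrinsic* (tonic) units fire regularly and are exempt from
the hypoxic rate multiplier, emulating the disinhibited intrinsically
active neurons that occasionally dominate hypoxic recordings at 1–3
electrodes. No calibrated rate is claimed for them (the phenomenon is
only qualitatively described); the default (4 spikes/s) simply makes
the focal-electrode filter testable.

### Hypoxia protocol

Oxygen pressure relaxes exponentially between set-points: 160 mmHg at
baseline, 23 mmHg at the severe-hypoxia plateau, time constants 0.95 h
downward and 0.51 h upward. Two multipliers track pO2 linearly between
the set-points: $\varepsilon(t)$ on all coupling strengths and a second
on baseline rates, each equal to 1 in normoxia and to a configured
plateau value (default 0.5) in deep hypoxia. Because network activity
is amplified by recurrent coupling (expected total rate scales as
$1/(1-\rho)$ with $\rho$ the mean per-spike branching ratio), halving
both rates and efficacy suppresses the array-wide firing rate *below*
50% of baseline, reproducing the qualitative observation that a
six-hour episode halves activity. Per-unit terminal fates are
prescribed, not emergent: optional silencing onsets (firing stops) and
deformation onsets (waveform amplitude decays 6%/h while the shape
widens 8%/h) emulate the late, irreversible phase.

### Stimulus responses

Stimulation occupies the first 10 minutes of every clock hour: each
selected electrode receives 40 biphasic pulses at 5–7-s intervals, in
random electrode order. Evoked activity per pulse has an early direct
component (< 15 ms, Poisson count, independent of hypoxia) and a late
synaptically mediated component (15–150 ms) whose expected count scales
with $\varepsilon(t)$. Evoked spikes are merged with the spontaneous
train, so post-stimulus histograms contain realistic spontaneous
background and evoked spikes themselves recruit cascades.

### What the generator does not emulate

Network-wide synchronous bursting beyond branching cascades,
electrode-noise correlations, multi-unit electrodes (except dedicated
variability fixtures), LFP/artefact waveforms, oxygen diffusion
gradients, and any biochemistry of cell death. Passing tests show the
*analysis* is correct and the *statistical* structure it assumes is
recoverable; they do not validate biological conclusions about real
cultures.

## Analysis methods

### Spike detection

Spikes are detected where the absolute signal exceeds 5.5× the
estimated noise level. The noise estimator is the median absolute
deviation divided by 0.6745 over 10-s windows (median across windows):
the real-time estimator used at acquisition is not specified in detail,
and MAD is the standard spike-robust choice — a documented stand-in,
not a reconstruction. The peak is the local maximum of $|x|$ within the
supra-threshold episode; the stored cutout spans 96 samples (6 ms at
16 kHz) from 2 ms before the peak (cutout sample 33) to 4 ms after.
A 1-ms dead time follows each peak; crossings inside it are absorbed
into the previous event (larger extremum wins). Under additive noise
the episode argmax scatters by a sample or two around the true peak
(neighbouring template samples differ by fractions of the noise SD), so
round-trip tests score recovery within ±3 samples (0.19 ms).

Artefact screening is a simplified two-rule stand-in for full offline
artefact classification: events coincident within ±0.2 ms on more than
`k` electrodes (default 6) with near-identical waveforms are rejected
as common electrical pickup, and clipped cutouts (≥ 4 consecutive
samples pinned at the extremum) are rejected as saturation.

### Array-wide firing rate (AWFR)

Total spikes over all electrodes in 30-min bins aligned to experiment
start, normalized to the mean over complete baseline bins; a partial
trailing bin is reported but never enters means. Focally hyperactive
electrodes are flagged by an explicit rule (the phenomenon is described
post hoc in the source literature without a numeric criterion): an
electrode whose hypoxia-phase mean rate exceeds its baseline rate while
the median normalized rate of the remaining electrodes is below 0.75.
Both thresholds are configurable and recorded; global elevation flags
nothing.

### Functional connectivity

Recordings are split into data blocks of exactly 10,000 spikes
(remainder dropped) so every connectivity estimate rests on equal
evidence regardless of activity suppression; electrodes with ≥ 50
spikes in a block are *active*. For each ordered active pair $(i,j)$,
$CFP_{ij}[\tau]$ is the fraction of $i$-spikes followed by at least one
$j$-spike in the latency bin $(\tau, \tau+0.5\,\mathrm{ms}]$, over a
0–500 ms window (both configurable; these follow the CFP methodology
this analysis descends from, which the source adapts only by shrinking
the block size). A connection's strength $S_{ij}$ is the curve maximum
and its latency $T_{ij}$ the delay of that maximum (upper bin edge;
earliest bin on ties).

When is $S_{ij} \neq 0$? The source never states its acceptance rule,
so the package defines a calibrated one: the peak's follower count must
exceed the $1-\alpha/n_{\mathrm{bins}}$ Poisson quantile of the chance
level estimated from the final 20% of the latency window
(Bonferroni-corrected to a family-wise $\alpha = 0.05$ per ordered
pair), and must comprise at least 5 follower events. A simpler
"tail mean + 3 SD" peak rule was considered and rejected: with ~1,000
latency bins per curve the expected number of chance bins above 3 SD is
already > 1, so that rule's per-pair false-positive rate is near 1
rather than the nominal 5%. The Poisson tail bound holds the measured
null detection rate at ~2–3% and recovers planted edges of follow
probability ≥ 0.25 with essentially full sensitivity in 30-min runs.

The connection count is the number of nonzero strengths. The
similarity index between blocks $A$ and $B$ is
$SI = |\{S_A \neq 0\} \cap \{S_B \neq 0\}|^2 / (N_A N_B)$ — the
squared-overlap reading of the published formula, adopted because it is
the reading under which $SI \in [0,1]$ with $SI = 1$ exactly when the
connection sets coincide (the printed typography is ambiguous; this
choice is flagged rather than asserted as the authors' intent). SI is
undefined (NA, with a warning) when either block has no connections,
and block pairs below 30 connections are excluded at the pipeline
level. Strengths are normalized per connection by the mean over
baseline blocks with zeros included, which pins every connection's
baseline mean at exactly 1; connections absent throughout baseline
cannot be normalized and are reported separately as new.

### Waveform integrity

An electrode records *single-neuron* activity when its first baseline
hour has ≥ 100 spikes, no inter-spike interval violates 1 ms, and the
waveform variability statistic is below 1. The statistic weights the
per-sample SD of the cutouts by the mean waveform over samples 9–59
(1.5 ms before to ~1.6 ms after the peak at sample 33), divided by the
peak amplitude of the mean. As printed the statistic carries signal
units (numerator ~ signal², denominator ~ signal); the package
therefore amplitude-normalizes cutouts (divides by max |mean waveform|)
before applying it, making the result dimensionless so a unit threshold
is meaningful across amplitudes. Whether the original computation
normalized is unstated; the choice is recorded here and the threshold
is configurable. On fixtures, mixtures of two templates always score
above a single template at equal noise, which is the property the
screen exists for.

Per single-neuron electrode, hourly mean waveforms (hours with ≥ 5
spikes; stimulation-segment spikes excluded) are tracked. The shape
counts as constant while its mean Pearson correlation with *all
preceding* non-missing hourly means stays above 0.9 and its amplitude
stays at or above 80% of the baseline value (mean amplitude over
baseline-phase hours). Missing hours are skipped, never counted as
violations. Fates partition exhaustively: units firing to the end with
no violation are `active_throughout`; silent tails are
`inactive_after_change` when a constancy violation precedes the
silence, else `inactive_no_change`. Whether post-hypoxia shapes should
be correlated against hypoxia-phase hours is unstated in the source;
the package correlates against all preceding non-missing hours.

### Excitatory/inhibitory classification

The Fano factor here is the ratio of the *standard deviation* (sample
SD, n−1) to the mean of spike counts in 6-s bins — as printed, not the
variance-to-mean ratio. Thresholds derive from reference population
values for mouse cortical cultures: excitatory 3.17 ± 2.02, inhibitory
29.37 ± 8.45, giving excitatory < 7.21 (= 3.17 + 2·2.02) and
inhibitory > 12.47 (= 29.37 − 2·8.45), with `unknown` between. The
counting window is the baseline phase only — the source does not name
its window, and classifying before the perturbation keeps class labels
independent of hypoxic fate; the window is configurable. Fate tables
report exact-ratio fractions per class and flag empty classes rather
than emitting 0/0.

### Stimulus-response quantification

The array-wide post-stimulus time histogram averages spike counts per
1-ms latency bin over a block's pulses; latencies below 2 ms are
blanked on all electrodes (stimulation artefacts are not analysable as
spikes). $A_{syn}$ is the sum of the averaged counts over the half-open
window [15, 150) ms — the expected synaptically mediated spike count
per pulse; the early direct phase is excluded because it mixes directly
and synaptically activated spikes, and is not analysed further. The
1-ms bin width is a convention: the windowed sum is bin-width-invariant
by construction. Each stimulation electrode's series is normalized to
its baseline mean; electrodes with baseline $A_{syn} < 6$ spikes are
flagged excluded (unstable normalization).

### Pipeline and group summaries

`run_experiment()` turns one configuration (generator + protocol +
analysis parameters + seed) into a result bundle: AWFR with focal
flags, per-block connectivity with SI-to-baseline and normalized
strengths, the $A_{syn}$ series, and unit profiles when waveforms are
attached. A configuration fully determines its outputs; identical
configs produce byte-identical bundles. Group summaries are mean ± SEM
per time bin with normalization done per replicate before averaging;
inferential statistics beyond SEM are intentionally out of scope — the
outputs are tidy tables any statistics package can consume.

## Numerical conventions and degenerate inputs

* Latency bins are half-open $(\tau, \tau+\Delta]$; the $A_{syn}$
  window is $[15, 150)$ ms; AWFR bins are left-closed. Ties in CFP
  argmax resolve to the earliest bin.
* Zero baseline activity makes AWFR normalization undefined: flagged,
  not silently 0. Same for SI with an empty connection set and for
  fate fractions of an empty class.
* A constant trace yields noise sigma 0 and detection refuses to
  threshold it. Traces shorter than one cutout are rejected; peaks
  whose cutout would run off the trace are dropped.
* Recordings are reproducible byte-for-byte from (config, seed); child
  streams for sub-simulations are drawn deterministically from the
  master seed.

## Problem sizes used by the test battery

The verification suite was sized to be decisive yet quick: CFP oracle
equivalence on 50 random blocks of ≤ 2,000 spikes; planted-edge
recovery on 20 units × 30 min (≥ 10 blocks); E/I recovery on 50 units
per class × 4 h; detection round trips on 10 × 60-s traces; the
hypoxia round trip on 30 units over 1 h baseline / 3 h hypoxia / 2 h
recovery. The settled-hypoxia readouts deliberately skip the first
hypoxic hour, where the pO2 relaxation (tau ≈ 1 h) still dominates, and
the recovery readout uses the final stimulation block, one hour past
restoration (tau up ≈ 0.5 h).

## Known limitations

The branching coupling model has no inhibitory synaptic dynamics (an
inhibitory *class* exists for firing statistics, but suppressive edges
are not part of the default wiring), no conduction-delay distributions
beyond per-edge constants, and no homeostatic plasticity — the partial
recovery of activity seen mid-hypoxia in real cultures must be supplied
through the protocol's multiplier curves rather than emerging. CFP, as
a pairwise statistic, reports indirect (two-step) influence as a
connection; the planted-edge suites therefore use disjoint edges, and
real-data interpretations should treat $S$ as functional, not
anatomical. The artefact screen and the noise estimator are documented
stand-ins chosen for robustness, not reconstructions of the original
acquisition software.
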