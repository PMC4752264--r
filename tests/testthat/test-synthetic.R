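test_that("identical seeds and configs give identical recordings", {
  gt <- network_ground_truth(n_units = 10, seed = 1)
  pr <- normoxic_protocol(0.5)
  a <- simulate_spontaneous(gt, pr, duration_h = 0.5, seed = 7)
  b <- simulate_spontaneous(gt, pr, duration_h = 0.5, seed = 7)
  expect_identical(a$spikes, b$spikes)
  c <- simulate_spontaneous(gt, pr, duration_h = 0.5, seed = 8)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("uncoupled normoxic units fire at their base rate", {
  pr <- normoxic_protocol(0.5)
  gt <- network_ground_truth(n_units = 3, frac_inhibitory = 0, n_edges = 0,
                             base_rate_range = c(2, 2), seed = 3)
  total <- 0L
  for (s in 1:20)
    total <- total + nrow(simulate_spontaneous(gt, pr, duration_h = 0.5,
                                               seed = 100 + s)$spikes)
  expected <- 3 * 2 * 1800 * 20               # units x rate x s x runs
  z <- (total - expected) / sqrt(expected)    # Poisson counts
  expect_lt(abs(z), 3)
})

test_that("a planted high-strength edge produces followers at its delay", {
  pr <- normoxic_protocol(0.5)
  gt <- network_ground_truth(
    n_units = 2, n_electrodes = 2, frac_inhibitory = 0,
    base_rate_range = c(2, 2),
    edges = data.frame(from = 1, to = 2, strength = 0.9, delay_ms = 5),
    seed = 4)
  gt$base_rate[2] <- 0  # unit 2 only fires when triggered
  rec <- simulate_spontaneous(gt, pr, duration_h = 0.5, seed = 11)
  ti <- rec$spikes$time_s[rec$spikes$unit == 1]
  tj <- rec$spikes$time_s[rec$spikes$unit == 2]
  expect_gt(length(tj), 1000)
  lags_ms <- vapply(tj, function(t) min(t - ti[ti < t]), numeric(1)) * 1000
  expect_true(all(lags_ms <= 5.6))            # never later than the parent
  expect_gt(mean(lags_ms > 4.4), 0.95)        # almost all at the edge delay
})

test_that("the merged train respects the 1-ms refractory period per unit", {
  gt <- network_ground_truth(n_units = 15, seed = 5,
                             strength_range = c(0.3, 0.5))
  rec <- simulate_spontaneous(gt, normoxic_protocol(0.5), duration_h = 0.5,
                              seed = 21)
  for (u in unique(rec$spikes$unit)) {
    tt <- sort(rec$spikes$time_s[rec$spikes$unit == u])
    if (length(tt) > 1) expect_gte(min(diff(tt)), 1e-3)
  }
})

test_that("generator rejects degenerate inputs", {
  gt <- network_ground_truth(n_units = 2, seed = 1)
  pr <- normoxic_protocol(1)
  expect_error(simulate_spontaneous(gt, pr, duration_h = 0, seed = 1),
               "positive")
  expect_error(simulate_spontaneous(gt, pr, duration_h = -1, seed = 1),
               "positive")
  expect_error(simulate_spontaneous(NULL, pr, duration_h = 1, seed = 1),
               "empty")
  expect_error(simulate_spontaneous(gt, pr, duration_h = 1), "seed")
})

test_that("an all-zero response kernel reproduces the spontaneous-only law", {
  gt <- network_ground_truth(n_units = 6, seed = 6)
  pr <- normoxic_protocol(1)
  set.seed(1); sched <- stimulation_schedule(c(2L, 4L), n_hours = 1)
  spont <- simulate_spontaneous(gt, pr, duration_h = 1, seed = 33)
  both <- simulate_stimulus_responses(
    gt, sched, pr, duration_h = 1, seed = 33,
    kernel = response_kernel(early_mean = 0, late_mean = 0))
  expect_identical(spont$spikes, both$spikes)
})

test_that("evoked late responses match the kernel's expected count", {
  # near-silent background so evoked spikes dominate the count
  gt <- network_ground_truth(n_units = 20, frac_inhibitory = 0, n_edges = 0,
                             base_rate_range = c(0.01, 0.01), seed = 7)
  pr <- normoxic_protocol(1)
  set.seed(2); sched <- stimulation_schedule(5L, n_hours = 1)
  rec <- simulate_stimulus_responses(
    gt, sched, pr, duration_h = 1, seed = 44,
    kernel = response_kernel(early_mean = 0, late_mean = 10))
  pulses <- sched$time_s
  late <- vapply(pulses, function(tp)
    sum(rec$spikes$time_s > tp + 0.015 & rec$spikes$time_s <= tp + 0.150),
    numeric(1))
  # mean of 40 Poisson(10) draws: SE = sqrt(10/40) = 0.5
  expect_lt(abs(mean(late) - 10), 3 * sqrt(10 / length(pulses)))
})

test_that("late-component counts scale with the efficacy multiplier", {
  gt <- network_ground_truth(n_units = 20, frac_inhibitory = 0, n_edges = 0,
                             base_rate_range = c(0.01, 0.01), seed = 8)
  kern <- response_kernel(early_mean = 0, late_mean = 10)
  # immediate plateau: tau so small the whole hypoxic hour sits at 0.5
  tl <- phase_timeline(1, 1, 0)
  pr_half <- hypoxia_protocol(tl, tau_down = 1e-3, efficacy_hypoxia = 0.5,
                              rate_hypoxia = 1)
  set.seed(3); sched <- stimulation_schedule(5L, n_hours = 2)
  rec <- simulate_stimulus_responses(gt, sched, pr_half, duration_h = 2,
                                     seed = 55, kernel = kern)
  count_late <- function(hour) {
    pulses <- sched$time_s[sched$hour == hour]
    mean(vapply(pulses, function(tp)
      sum(rec$spikes$time_s > tp + 0.015 & rec$spikes$time_s <= tp + 0.150),
      numeric(1)))
  }
  ratio <- count_late(1) / count_late(0)
  expect_lt(abs(ratio - 0.5), 0.15)
})

test_that("rendered traces are noise plus templates at the spike times", {
  gt <- network_ground_truth(n_units = 2, n_electrodes = 2, n_edges = 0,
                             frac_inhibitory = 0,
                             base_rate_range = c(0.5, 0.5), seed = 9)
  pr <- normoxic_protocol(1)
  rec <- simulate_spontaneous(gt, pr, duration_h = 10 / 3600, seed = 66)
  # noise-only electrode statistics
  empty <- rec
  empty$spikes <- rec$spikes[0, ]
  tr0 <- render_raw_traces(empty, noise_sd = 2, seed = 1,
                           electrodes = 1L)[["1"]]
  expect_lt(abs(mean(tr0)), 0.1)
  expect_lt(abs(sd(tr0) - 2), 0.1)
  # single spike, zero noise: the trace is the template at the placement
  one <- rec
  one$spikes <- data.frame(time_s = 0.05, electrode = 1L, unit = 1L,
                           evoked = FALSE)
  tr1 <- render_raw_traces(one, noise_sd = 0, seed = 1,
                           electrodes = 1L)[["1"]]
  peak <- round(0.05 * 16000) + 1L
  expect_equal(tr1[(peak - 32):(peak + 63)], gt$template[1, ])
  expect_true(all(tr1[-((peak - 32):(peak + 63))] == 0))
  expect_error(render_raw_traces(one, noise_sd = -1, seed = 1), "negative")
})

test_that("stimulation schedules stay inside the 10-min segment", {
  set.seed(4)
  sched <- stimulation_schedule(c(1L, 2L), n_hours = 3)
  expect_true(all(diff(sched$time_s[sched$hour == 1]) > 0))
  for (h in 0:2) {
    tt <- sched$time_s[sched$hour == h] - h * 3600
    expect_true(all(tt > 0 & tt < 600))
  }
  expect_error(stimulation_schedule(1:5, n_hours = 1), "10-min")
})
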