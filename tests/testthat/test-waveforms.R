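test_that("identical cutouts give zero variability; formula matches oracle", {
  tpl <- ap_template(amplitude = 60)
  W <- matrix(rep(tpl, 200), 200, 96, byrow = TRUE)
  expect_equal(compute_variability(W), 0)

  set.seed(40)
  Wn <- W + rnorm(length(W), 0, 3)
  v <- compute_variability(Wn)
  expect_gt(v, 0)
  expect_equal(v, brute_variability(Wn))
  # invariant under a global sign flip
  expect_equal(compute_variability(-Wn), v)
  expect_error(compute_variability(matrix(0, 10, 96)), "zero-amplitude")
  expect_error(compute_variability(W[1, , drop = FALSE]), "at least 2")
})

test_that("two-template mixtures score higher than a single template", {
  set.seed(41)
  tplA <- ap_template(amplitude = 60, rebound = 0.4)
  tplB <- -ap_template(amplitude = 55, rebound = 0.45)  # opposite polarity lobes
  noise <- function(n) matrix(rnorm(n * 96, 0, 3), n, 96)
  single <- matrix(rep(tplA, 200), 200, 96, byrow = TRUE) + noise(200)
  mix <- rbind(matrix(rep(tplA, 100), 100, 96, byrow = TRUE),
               matrix(rep(tplB, 100), 100, 96, byrow = TRUE)) + noise(200)
  expect_gt(compute_variability(mix), compute_variability(single))
})

test_that("single-neuron screening enforces all three criteria", {
  tl <- phase_timeline(2, 0, 0)
  tpl <- ap_template(amplitude = 60)
  mk <- function(n, isi = 0.5) {
    sp <- data.frame(time_s = seq(1, by = isi, length.out = n),
                     electrode = 1L)
    set.seed(42)
    W <- matrix(rep(tpl, n), n, 96, byrow = TRUE) + rnorm(n * 96, 0, 3)
    make_recording(sp, n_electrodes = 1, duration_h = 2, timeline = tl,
                   waveforms = W)
  }
  ok <- single_neuron_screen(mk(120), 1L)
  expect_true(ok$is_single_neuron)
  expect_equal(ok$refractory_violations, 0L)
  expect_lt(ok$variability, 1)

  # 99 spikes in baseline hour 1: rejected regardless of variability
  few <- single_neuron_screen(mk(99), 1L)
  expect_equal(few$n_spikes_baseline_h1, 99L)
  expect_false(few$is_single_neuron)

  # refractory violations: two spikes 0.5 ms apart
  rec <- mk(120)
  rec$spikes$time_s[2] <- rec$spikes$time_s[1] + 0.0005
  viol <- single_neuron_screen(rec, 1L)
  expect_equal(viol$refractory_violations, 1L)
  expect_false(viol$is_single_neuron)
})

# Hour-by-hour recording with a prescribed per-hour amplitude scale and
# widening; zero noise so constancy crossings are exact.
tracked_fixture <- function(n_hours, amp_scale, width = rep(1, n_hours),
                            n_per_hour = 10, baseline_h = 2) {
  tpl <- ap_template(amplitude = 60)
  sp <- NULL; W <- NULL
  for (h in seq_len(n_hours) - 1L) {
    if (is.na(amp_scale[h + 1])) next         # silent hour
    w <- morph_template(tpl, hours_past_onset = (width[h + 1] - 1) / 0.08,
                        amp_loss_per_h = 0) * amp_scale[h + 1]
    sp <- rbind(sp, data.frame(
      time_s = h * 3600 + seq(1800, 1800 + n_per_hour - 1),
      electrode = 1L))
    W <- rbind(W, matrix(rep(w, n_per_hour), n_per_hour, 96, byrow = TRUE))
  }
  make_recording(sp, n_electrodes = 1, duration_h = n_hours,
                 timeline = phase_timeline(baseline_h, n_hours - baseline_h, 0),
                 waveforms = W)
}

test_that("a constant template tracks as constant throughout", {
  rec <- tracked_fixture(6, amp_scale = rep(1, 6))
  tr <- track_shape(rec, 1L)
  present <- !tr$hours$missing
  expect_true(all(tr$hours$r_mean[present][-1] == 1))
  expect_true(all(tr$hours$constant[present]))
  expect_true(is.na(tr$first_violation_h))
  expect_equal(assign_fate(tr)$fate, "active_throughout")
})

test_that("amplitude loss below 80% of baseline is caught at the right hour", {
  # amplitude 1.0 for hours 0-19, then 0.70: violation exactly at hour 20
  rec <- tracked_fixture(24, amp_scale = c(rep(1, 20), rep(0.70, 4)))
  tr <- track_shape(rec, 1L)
  expect_equal(tr$first_violation_h, 20)
  expect_equal(tr$constant_until_h, 19)
})

test_that("progressive widening is caught when correlation drops", {
  widths <- c(rep(1, 10), seq(1.1, 3.0, length.out = 14))
  rec <- tracked_fixture(24, amp_scale = rep(1, 24), width = widths)
  tr <- track_shape(rec, 1L)
  expect_false(is.na(tr$first_violation_h))
  # the violation hour is the first whose mean correlation fell to 0.9
  h <- tr$first_violation_h
  expect_lte(tr$hours$r_mean[h + 1], 0.9)
  pres <- which(!tr$hours$missing & tr$hours$hour < h)
  expect_true(all(tr$hours$r_mean[pres][-1] > 0.9))
})

test_that("missing hours are skipped without breaking constancy", {
  amp <- rep(1, 10); amp[c(4, 5)] <- NA      # two silent hours
  rec <- tracked_fixture(10, amp_scale = amp)
  tr <- track_shape(rec, 1L)
  expect_true(all(tr$hours$missing[c(4, 5)]))
  expect_true(all(tr$hours$constant[!tr$hours$missing]))
  expect_true(is.na(tr$first_violation_h))
})

test_that("fates partition into the three categories", {
  # silence from hour 8 with a violation at hour 6: change precedes death
  rec <- tracked_fixture(12, amp_scale = c(rep(1, 6), 0.5, 0.5, rep(NA, 4)))
  tr <- track_shape(rec, 1L)
  f <- assign_fate(tr, 12)
  expect_equal(tr$first_violation_h, 6)
  expect_equal(f$inactive_from_h, 8)
  expect_equal(f$fate, "inactive_after_change")

  # silence from hour 5 with no prior violation
  rec2 <- tracked_fixture(12, amp_scale = c(rep(1, 5), rep(NA, 7)))
  tr2 <- track_shape(rec2, 1L)
  f2 <- assign_fate(tr2, 12)
  expect_equal(f2$fate, "inactive_no_change")
  expect_equal(f2$inactive_from_h, 5)
})
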