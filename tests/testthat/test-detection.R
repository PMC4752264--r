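test_that("noise estimation is accurate and robust to spikes", {
  set.seed(10)
  tr <- rnorm(16000 * 12, 0, 4)
  est <- estimate_noise(tr)
  expect_lt(abs(est$sigma - 4) / 4, 0.05)

  # 1% of samples carry large spikes: MAD stays put, plain SD does not
  tr2 <- tr
  idx <- sample(length(tr2), length(tr2) * 0.01)
  tr2[idx] <- tr2[idx] + sample(c(-40, 40), length(idx), replace = TRUE)
  est2 <- estimate_noise(tr2)
  expect_lt(abs(est2$sigma - 4) / 4, 0.10)
  expect_gt(sd(tr2), 1.10 * 4)

  expect_error(estimate_noise(numeric(0)), "empty")
  expect_error(estimate_noise(rnorm(100)), "1 s")
})

test_that("a constant trace yields sigma 0 and blocks thresholding", {
  est <- estimate_noise(rep(1, 16000))
  expect_equal(est$sigma, 0)
  expect_error(detect_spikes(rep(1, 16000), est), "positive")
})

test_that("bounded noise below threshold yields zero events", {
  set.seed(11)
  tr <- truncated_noise(16000 * 5, sd = 1, bound_sd = 5)
  det <- detect_spikes(tr, estimate_noise(tr))
  expect_equal(nrow(det$events), 0)
})

test_that("planted biphasic spikes are each detected once at their peak", {
  set.seed(12)
  tpl <- ap_template(amplitude = 10, rebound = 0.25)
  # noise bounded at 2.5 sigma: rebound (2.5) + noise can never cross
  # 5.5 sigma, so retriggering and >2-sample peak shifts are impossible
  tr <- truncated_noise(16000 * 2, sd = 1, bound_sd = 2.5)
  at <- c(5000, 12000)                         # two spikes ~440 ms apart
  for (s in at) tr[(s - 32):(s + 63)] <- tr[(s - 32):(s + 63)] + tpl
  det <- detect_spikes(tr, estimate_noise(tr))
  expect_equal(nrow(det$events), 2)
  expect_true(all(abs(det$events$peak_sample - at) <= 2))
  expect_equal(dim(det$waveforms), c(2L, 96L))
  # the cutout peak sits at sample 33 and is the cutout's absolute max
  expect_equal(apply(abs(det$waveforms), 1, which.max), c(33L, 33L))

  # two spikes 20 ms apart remain two events
  tr2 <- truncated_noise(16000, sd = 1, bound_sd = 2.5)
  at2 <- c(6000, 6320)
  for (s in at2) tr2[(s - 32):(s + 63)] <- tr2[(s - 32):(s + 63)] + tpl
  det2 <- detect_spikes(tr2, estimate_noise(tr2))
  expect_equal(nrow(det2$events), 2)
})

test_that("detection matches the sample-by-sample oracle", {
  set.seed(13)
  tpl <- ap_template(amplitude = 8)
  for (rep in 1:6) {
    tr <- rnorm(16000 * 5)
    at <- sort(sample(200:(16000 * 5 - 200), 40))
    for (s in at) {
      lo <- max(1, s - 32); hi <- min(length(tr), s + 63)
      tr[lo:hi] <- tr[lo:hi] + tpl[(lo - (s - 32) + 1):(96 - (s + 63 - hi))]
    }
    sigma <- estimate_noise(tr)$sigma
    fast <- detect_spikes(tr, sigma)$events$peak_sample
    slow <- brute_detect(tr, sigma)
    expect_identical(fast, slow)
  }
})

test_that("detection recovers >=8-sigma spikes with no false positives", {
  set.seed(14)
  n_fp <- 0L; hit <- 0L; planted <- 0L
  for (s in 1:3) {
    # noise-only trace, bounded below threshold
    tr0 <- truncated_noise(16000 * 30, sd = 2, bound_sd = 5)
    n_fp <- n_fp + nrow(detect_spikes(tr0, estimate_noise(tr0))$events)
    # 8-sigma spikes in unbounded Gaussian noise
    tr <- rnorm(16000 * 30, 0, 2)
    tpl <- ap_template(amplitude = 16)
    at <- seq(1000, length(tr) - 1000, by = 4800)
    for (p in at) tr[(p - 32):(p + 63)] <- tr[(p - 32):(p + 63)] + tpl
    det <- detect_spikes(tr, estimate_noise(tr))
    hit <- hit + sum(vapply(at, function(p)
      any(abs(det$events$peak_sample - p) <= 3), logical(1)))
    planted <- planted + length(at)
  }
  expect_equal(n_fp, 0L)
  expect_gte(hit / planted, 0.99)
})

test_that("artefact screening rejects coincidences and clipping only", {
  set.seed(15)
  tpl <- ap_template(amplitude = 50)
  # ordinary events on distinct electrodes, no coincidence: all kept
  ev <- data.frame(time_s = seq(0.1, 1, by = 0.1), electrode = rep(1:5, 2))
  W <- matrix(rep(tpl, 10), 10, 96, byrow = TRUE) + rnorm(960)
  scr <- screen_artefacts(ev, W)
  expect_equal(scr$kept, 1:10)

  # identical waveform on 30 electrodes at one instant: all rejected
  ev2 <- rbind(ev, data.frame(time_s = rep(2.00001, 30), electrode = 1:30))
  W2 <- rbind(W, matrix(rep(tpl, 30), 30, 96, byrow = TRUE))
  scr2 <- screen_artefacts(ev2, W2)
  expect_equal(scr2$rejected, 11:40)
  expect_equal(scr2$kept, 1:10)

  # saturated square cutout: rejected
  sat <- c(rep(0, 20), rep(-120, 30), rep(0, 46))
  scr3 <- screen_artefacts(data.frame(time_s = 0.5, electrode = 3),
                           matrix(sat, 1, 96))
  expect_equal(scr3$rejected, 1L)
})
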