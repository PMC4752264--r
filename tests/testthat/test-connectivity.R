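test_that("block partitioning drops remainders and screens active electrodes", {
  set.seed(30)
  tl <- phase_timeline(1, 0, 0)
  spikes <- data.frame(time_s = sort(runif(25000, 0, 3600)),
                       electrode = sample(1:30, 25000, replace = TRUE))
  rec <- make_recording(spikes, duration_h = 1, timeline = tl)
  blocks <- partition_blocks(rec)
  expect_length(blocks, 2)
  expect_equal(nrow(blocks[[1]]$spikes), 10000)

  rec2 <- make_recording(spikes[1:9999, ], duration_h = 1, timeline = tl)
  expect_warning(b2 <- partition_blocks(rec2), "fewer than one")
  expect_length(b2, 0)

  # 49 spikes on electrode 2 in the block: excluded; 50 on electrode 3: kept
  sp3 <- data.frame(
    time_s = sort(runif(1000, 0, 100)),
    electrode = c(rep(2L, 49), rep(3L, 50), rep(1L, 901)))
  rec3 <- make_recording(sp3, n_electrodes = 3, duration_h = 1, timeline = tl)
  b3 <- partition_blocks(rec3, block_size = 1000L)
  expect_false(2L %in% b3[[1]]$active)
  expect_true(all(c(1L, 3L) %in% b3[[1]]$active))
})

test_that("CFP curves match the definition on simple constructions", {
  # j never fires within tau_max of any i spike
  sp <- data.frame(time_s = c(seq(1, 50, by = 1), 0.2),
                   electrode = c(rep(1L, 50), 2L))
  blk <- make_block(sp, active = 1:2, n_electrodes = 2)
  expect_true(all(cfp_curve(compute_cfp(blk), 1, 2) == 0))

  # deterministic follower at exactly 5 ms: p = 1 in the 5-ms bin
  ti <- seq(1, 60, by = 1)
  sp2 <- data.frame(time_s = c(ti, ti + 0.005),
                    electrode = rep(c(1L, 2L), each = length(ti)))
  cfp <- compute_cfp(make_block(sp2, active = 1:2, n_electrodes = 2))
  p <- cfp_curve(cfp, 1, 2)
  expect_equal(p[10], 1)                       # bin (4.5, 5.0] ms
  expect_true(all(p[seq_along(p) != 10] <= 0.05))
  con <- extract_connections(cfp)
  expect_equal(con$S[1, 2], 1)
  expect_equal(con$T_ms[1, 2], 5)
  expect_equal(con$N, sum(con$S != 0))
})

test_that("fast CFP equals the O(n^2) brute-force counter", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(300:1500, 1)
    ne <- sample(3:5, 1)
    sp <- data.frame(time_s = sort(runif(n, 0, n / 20)),
                     electrode = sample(seq_len(ne), n, replace = TRUE))
    blk <- make_block(sp, active = seq_len(ne), n_electrodes = ne)
    cfp <- compute_cfp(blk)
    for (i in seq_len(ne)) for (j in setdiff(seq_len(ne), i))
      expect_equal(cfp_curve(cfp, i, j), brute_cfp(sp, i, j))
  }
})

test_that("a planted 0.3-probability edge shows a CFP peak near 0.3", {
  pr <- normoxic_protocol(0.5)
  gt <- network_ground_truth(
    n_units = 2, n_electrodes = 2, frac_inhibitory = 0,
    base_rate_range = c(3, 3),
    edges = data.frame(from = 1, to = 2, strength = 0.3, delay_ms = 5.2),
    seed = 32)
  # average the follower mass around the planted delay over 5 seeds so the
  # binomial noise (SE ~ 0.006 per run) is well below the tested effect
  seeds <- 201:205
  mass <- n_i <- numeric(length(seeds))
  peak_bin <- integer(length(seeds))
  for (k in seq_along(seeds)) {
    rec <- simulate_spontaneous(gt, pr, duration_h = 0.5, seed = seeds[k])
    blk <- make_block(rec$spikes[, c("time_s", "electrode")],
                      active = 1:2, n_electrodes = 2)
    p <- cfp_curve(compute_cfp(blk), 1, 2)
    chance <- mean(p[801:1000])
    mass[k] <- sum(p[10:11]) - 2 * chance   # (4.5, 5.5] ms minus chance
    n_i[k] <- sum(rec$spikes$electrode == 1)
    peak_bin[k] <- which.max(p)
  }
  se <- sqrt(0.3 * 0.7 / sum(n_i))
  # 0.005 covers jitter mass outside the two bins plus refractory losses
  expect_lt(abs(mean(mass) - 0.3), 3 * se + 0.005)
  expect_true(all(peak_bin == 11L))            # bin (5.0, 5.5] ms
})

test_that("independent Poisson pairs are declared connected in <5% of runs", {
  set.seed(33)
  hits <- vapply(1:40, function(r) {
    n <- 2000
    sp <- data.frame(time_s = sort(runif(n, 0, 100)),
                     electrode = sample(1:2, n, replace = TRUE))
    m <- extract_connections(compute_cfp(
      make_block(sp, active = 1:2, n_electrodes = 2)))
    m$S[1, 2] != 0
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("connection counting and the hand similarity example are exact", {
  S0 <- matrix(0, 60, 60)
  expect_equal(connection_count(S0), 0)
  set.seed(34)
  S236 <- S0; S236[sample(3600, 236)] <- runif(236, 0.05, 0.4)
  expect_equal(connection_count(S236), 236)

  # |A| = |B| = 4, |A n B| = 2 -> SI = 4/16 = 0.25
  A <- matrix(0, 6, 6); B <- matrix(0, 6, 6)
  A[cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))] <- 1
  B[cbind(c(1, 2, 5, 6), c(2, 3, 4, 5))] <- 1
  expect_equal(similarity_index(A, B), 0.25)
})

test_that("similarity index is symmetric, bounded, and 1 on identity", {
  set.seed(35)
  for (r in 1:50) {
    A <- matrix(rbinom(100, 1, 0.2) * runif(100), 10, 10)
    B <- matrix(rbinom(100, 1, 0.2) * runif(100), 10, 10)
    if (sum(A != 0) == 0 || sum(B != 0) == 0) {
      expect_warning(expect_true(is.na(similarity_index(A, B))))
      next
    }
    si <- similarity_index(A, B)
    expect_gte(si, 0); expect_lte(si, 1)
    expect_equal(si, similarity_index(B, A))
    expect_equal(similarity_index(A, A), 1)
  }
  # disjoint sets give 0
  A <- matrix(0, 4, 4); B <- matrix(0, 4, 4)
  A[1, 2] <- 1; B[3, 4] <- 1
  expect_equal(similarity_index(A, B), 0)
})

test_that("strength normalization fixes the baseline mean at 1", {
  mk <- function(S, idx, phase) structure(
    list(S = S, T_ms = ifelse(S > 0, 5, NA), N = sum(S != 0),
         block_index = idx, mid_h = idx / 2, phase = phase),
    class = "connectivity_matrix")
  S <- matrix(0, 4, 4); S[1, 2] <- 0.2; S[3, 4] <- 0.4
  Shalf <- S / 2
  Snew <- S; Snew[2, 3] <- 0.1                 # appears only after baseline
  mats <- list(mk(S, 1, "baseline"), mk(S, 2, "baseline"),
               mk(Shalf, 3, "hypoxia"), mk(Snew, 4, "recovery"))
  ns <- normalize_strengths(mats, baseline_blocks = 1:2)
  expect_equal(ns$matrices[[1]]$S_norm[1, 2], 1)
  expect_equal(ns$matrices[[3]]$S_norm[1, 2], 0.5)
  expect_equal(ns$matrices[[3]]$S_norm[3, 4], 0.5)
  # per-connection baseline mean of normalized strengths is exactly 1
  expect_equal((ns$matrices[[1]]$S_norm[3, 4] +
                  ns$matrices[[2]]$S_norm[3, 4]) / 2, 1)
  expect_equal(unname(ns$new_connections[1, ]), c(2L, 3L))
  expect_true(is.na(ns$matrices[[4]]$S_norm[2, 3]))
})
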