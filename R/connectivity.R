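#' Partition a recording into fixed-spike-count data blocks
#'
#' Connectivity is estimated per data block of exactly `block_size`
#' spikes (10,000 by default), so that every block carries the same
#' amount of statistical evidence regardless of how strongly activity is
#' suppressed. The remainder after the last complete block is dropped.
#' Each block records its active-electrode set: electrodes with at least
#' `active_min` spikes (50 by default) inside the block.
#'
#' @param recording an `mea_recording` (spikes sorted by time)
#' @param block_size spikes per block
#' @param active_min minimum spikes for an electrode to count as active
#' @return list of `data_block` objects: `index`, `spikes` (data.frame
#'   `time_s`, `electrode`), `active`, `t_start_s`, `t_end_s`, `mid_h`,
#'   `phase`
#' @export
partition_blocks <- function(recording, block_size = 10000L,
                             active_min = 50L) {
  sp <- recording$spikes
  n_blocks <- floor(nrow(sp) / block_size)
  if (n_blocks == 0L) {
    warning("fewer than one complete block (", nrow(sp), " spikes)")
    return(list())
  }
  lapply(seq_len(n_blocks), function(b) {
    rows <- ((b - 1L) * block_size + 1L):(b * block_size)
    s <- sp[rows, c("time_s", "electrode")]
    cnt <- tabulate(s$electrode, nbins = recording$n_electrodes)
    mid_h <- (s$time_s[1] + s$time_s[block_size]) / 2 / 3600
    structure(list(
      index = b, spikes = s,
      active = which(cnt >= active_min),
      t_start_s = s$time_s[1], t_end_s = s$time_s[block_size],
      mid_h = mid_h,
      phase = if (!is.null(recording$timeline))
        phase_at(recording$timeline, mid_h) else NA_character_,
      n_electrodes = recording$n_electrodes
    ), class = "data_block")
  })
}

#' Conditional firing probabilities for all active electrode pairs
#'
#' For an ordered pair (i, j) of active electrodes, CFP[tau] is the
#' probability that electrode j fires at least one spike in the latency
#' bin (tau, tau + delta] given a spike on electrode i at time 0. All
#' spikes of i inside the block condition the estimate; each
#' (conditioning spike, bin) pair contributes at most once, so every
#' probability is bounded by 1.
#'
#' The result is stored sparsely (only bins with followers); use
#' [cfp_curve()] to densify one pair.
#'
#' @param block a `data_block` from [partition_blocks()]
#' @param tau_bin_ms latency bin width (ms)
#' @param tau_max_ms latency window (ms)
#' @param chunk_spikes internal chunk size bounding memory on very dense
#'   blocks
#' @return object of class `cfp_set`: data.table `counts`
#'   (`i`, `j`, `bin`, `count`), `n_src` conditioning-spike counts per
#'   electrode, `n_bins`, `tau_bin_ms`, `active`
#' @export
compute_cfp <- function(block, tau_bin_ms = 0.5, tau_max_ms = 500,
                        chunk_spikes = 250000L) {
  t <- block$spikes$time_s
  el <- block$spikes$electrode
  n <- length(t)
  n_bins <- as.integer(round(tau_max_ms / tau_bin_ms))
  tau_max_s <- tau_max_ms / 1000
  bin_s <- tau_bin_ms / 1000
  active <- block$active
  is_active <- logical(block$n_electrodes)
  is_active[active] <- TRUE
  n_src <- tabulate(el, nbins = block$n_electrodes)

  hi <- findInterval(t + tau_max_s + 1e-12, t)
  m <- hi - seq_len(n)
  pieces <- list(); pk <- 0L
  start <- 1L
  while (start <= n) {
    # chunk the conditioning spikes so the pair-event expansion stays small
    csum <- cumsum(as.numeric(m[start:n]))
    stop_k <- start + max(1L, findInterval(chunk_spikes, csum)) - 1L
    stop_k <- min(stop_k, n)
    ks <- start:stop_k
    mk <- m[ks]
    sel <- mk > 0L
    if (any(sel)) {
      src <- rep(ks[sel], mk[sel])
      tgt <- sequence(mk[sel], from = ks[sel] + 1L)
      lag <- t[tgt] - t[src]
      keep <- lag > 0 & el[src] != el[tgt] &
        is_active[el[src]] & is_active[el[tgt]]
      if (any(keep)) {
        src <- src[keep]; tgt <- tgt[keep]; lag <- lag[keep]
        bin <- as.integer(ceiling(lag / bin_s - 1e-9))
        bin[bin > n_bins] <- NA_integer_
        ok <- !is.na(bin)
        if (any(ok)) {
          dt <- data.table::data.table(
            k = src[ok], i = el[src[ok]], j = el[tgt[ok]], bin = bin[ok])
          dt <- unique(dt, by = c("k", "j", "bin"))
          pk <- pk + 1L
          pieces[[pk]] <- dt[, .N, by = c("i", "j", "bin")]
        }
      }
    }
    start <- stop_k + 1L
  }
  counts <- if (pk) {
    all <- data.table::rbindlist(pieces)
    all[, list(count = sum(N)), by = c("i", "j", "bin")]
  } else {
    data.table::data.table(i = integer(0), j = integer(0),
                           bin = integer(0), count = integer(0))
  }
  structure(list(counts = counts, n_src = n_src, n_bins = n_bins,
                 tau_bin_ms = tau_bin_ms, active = active,
                 n_electrodes = block$n_electrodes,
                 block_index = block$index, mid_h = block$mid_h,
                 phase = block$phase),
            class = "cfp_set")
}

#' Dense CFP curve for one ordered electrode pair
#' @param cfp a `cfp_set` from [compute_cfp()]
#' @param i,j source and target electrode ids (both active, i != j)
#' @return numeric vector of probabilities, one per latency bin
#' @export
cfp_curve <- function(cfp, i, j) {
  stopifnot(i != j)
  p <- numeric(cfp$n_bins)
  sel <- cfp$counts$i == i & cfp$counts$j == j
  if (any(sel))
    p[cfp$counts$bin[sel]] <- cfp$counts$count[sel] / cfp$n_src[i]
  p
}

#' Extract functional connections from CFP curves
#'
#' A connection's strength S is the maximum of the CFP curve and its
#' latency T the delay at which that maximum occurs (upper edge of the
#' bin; earliest bin on ties). The peak qualifies as a connection only if
#' its follower count exceeds a Poisson tail bound on the chance level
#' estimated from the final `tail_frac` of the latency window
#' (Bonferroni-corrected over bins to a family-wise level `alpha` per
#' ordered pair) and is supported by at least `min_followers` follower
#' events; otherwise S = 0.
#'
#' @param cfp a `cfp_set`
#' @param alpha family-wise false-positive level per ordered pair
#' @param min_followers minimum follower events at the peak
#' @param tail_frac trailing fraction of the window used to estimate the
#'   chance level
#' @return object of class `connectivity_matrix`: matrices `S`
#'   (strengths; 0 = no functional connection) and `T_ms` (latency at the
#'   maximum, NA where S = 0), connection count `N`, `block_index`,
#'   `mid_h`, `phase`
#' @export
extract_connections <- function(cfp, alpha = 0.05, min_followers = 5L,
                                tail_frac = 0.2) {
  ne <- cfp$n_electrodes
  S <- matrix(0, ne, ne)
  T_ms <- matrix(NA_real_, ne, ne)
  cnt <- cfp$counts
  if (nrow(cnt)) {
    tail_start <- ceiling((1 - tail_frac) * cfp$n_bins)
    n_tail <- cfp$n_bins - tail_start + 1L
    cnt_dt <- data.table::as.data.table(cnt)
    peaks <- cnt_dt[order(bin), list(
      peak = max(count),
      peak_bin = bin[which.max(count)],
      tail_sum = sum(count[bin >= tail_start])
    ), by = c("i", "j")]
    lambda <- cfp$n_src[peaks$i] * (peaks$tail_sum / (cfp$n_src[peaks$i] * n_tail))
    thr <- stats::qpois(1 - alpha / cfp$n_bins, lambda)
    sig <- peaks$peak > thr & peaks$peak >= min_followers
    if (any(sig)) {
      pi <- peaks$i[sig]; pj <- peaks$j[sig]
      S[cbind(pi, pj)] <- peaks$peak[sig] / cfp$n_src[pi]
      T_ms[cbind(pi, pj)] <- peaks$peak_bin[sig] * cfp$tau_bin_ms
    }
  }
  structure(list(S = S, T_ms = T_ms, N = sum(S != 0),
                 block_index = cfp$block_index, mid_h = cfp$mid_h,
                 phase = cfp$phase),
            class = "connectivity_matrix")
}

#' Single-pair connection extraction from a dense CFP curve
#'
#' Same significance rule as [extract_connections()], for one dense
#' curve; used for curve-level reasoning and testing.
#'
#' @param p dense probability curve (one value per bin)
#' @param n_src number of conditioning spikes behind the curve
#' @param tau_bin_ms latency bin width (ms)
#' @inheritParams extract_connections
#' @return list `(S, T_ms)`; S = 0 and T_ms = NA when no connection
#' @export
extract_connection <- function(p, n_src, tau_bin_ms = 0.5, alpha = 0.05,
                               min_followers = 5L, tail_frac = 0.2) {
  n_bins <- length(p)
  counts <- round(p * n_src)
  tail_start <- ceiling((1 - tail_frac) * n_bins)
  lambda <- mean(counts[tail_start:n_bins])
  thr <- stats::qpois(1 - alpha / n_bins, lambda)
  peak_bin <- which.max(counts)
  peak <- counts[peak_bin]
  if (peak > thr && peak >= min_followers)
    list(S = peak / n_src, T_ms = peak_bin * tau_bin_ms)
  else list(S = 0, T_ms = NA_real_)
}

#' Number of functional connections in a connectivity matrix
#' @param matrix_ a `connectivity_matrix` (or a plain strengths matrix)
#' @return integer count of nonzero strengths
#' @export
connection_count <- function(matrix_) {
  S <- if (inherits(matrix_, "connectivity_matrix")) matrix_$S else matrix_
  sum(S != 0)
}

#' Similarity index between two connectivity matrices
#'
#' SI = |A n B|^2 / (|A| * |B|), where A and B are the sets of electrode
#' pairs with nonzero strength in the two matrices. SI is 1 iff the sets
#' coincide, 0 iff they are disjoint, and lies in [0, 1] always. When
#' either matrix has no connections the index is undefined and NA is
#' returned with a warning.
#'
#' @param matrix_A,matrix_B `connectivity_matrix` objects or plain
#'   strengths matrices
#' @return similarity index in [0, 1], or NA when undefined
#' @export
similarity_index <- function(matrix_A, matrix_B) {
  SA <- if (inherits(matrix_A, "connectivity_matrix")) matrix_A$S else matrix_A
  SB <- if (inherits(matrix_B, "connectivity_matrix")) matrix_B$S else matrix_B
  nA <- sum(SA != 0)
  nB <- sum(SB != 0)
  if (nA == 0L || nB == 0L) {
    warning("similarity index undefined: a matrix has no connections")
    return(NA_real_)
  }
  inter <- sum(SA != 0 & SB != 0)
  inter^2 / (nA * nB)
}

#' Normalize connection strengths to their baseline means
#'
#' Each connection (i, j) is divided by its mean strength over the
#' baseline blocks (zeros included), so the baseline-phase mean of every
#' normalized connection is exactly 1. Connections never seen during
#' baseline cannot be normalized; they are left NA in the normalized
#' matrices and reported in the `new_connections` set.
#'
#' @param matrices list of `connectivity_matrix` objects (one per block)
#' @param baseline_blocks indices into `matrices` of the baseline blocks
#' @return list: `matrices` (normalized copies, `S_norm` added),
#'   `baseline_mean` matrix, `new_connections` two-column matrix of
#'   (i, j) pairs absent at baseline
#' @export
normalize_strengths <- function(matrices, baseline_blocks) {
  stopifnot(length(baseline_blocks) >= 1)
  base_mean <- Reduce(`+`, lapply(matrices[baseline_blocks], `[[`, "S")) /
    length(baseline_blocks)
  any_nonzero <- Reduce(`|`, lapply(matrices, function(m) m$S != 0))
  new_conn <- which(any_nonzero & base_mean == 0, arr.ind = TRUE)
  out <- lapply(matrices, function(m) {
    m$S_norm <- ifelse(base_mean > 0, m$S / base_mean, NA_real_)
    m$S_norm[m$S == 0 & base_mean == 0] <- NA_real_
    m
  })
  list(matrices = out, baseline_mean = base_mean,
       new_connections = new_conn)
}

#' Per-block connectivity over a whole recording
#'
#' Runs [partition_blocks()], [compute_cfp()] and [extract_connections()]
#' and returns the block series plus a tidy summary.
#'
#' @inheritParams partition_blocks
#' @inheritParams compute_cfp
#' @inheritParams extract_connections
#' @return list: `matrices` (per block), `summary` data.frame
#'   (`block`, `mid_h`, `phase`, `n_connections`)
#' @export
connectivity_series <- function(recording, block_size = 10000L,
                                active_min = 50L, tau_bin_ms = 0.5,
                                tau_max_ms = 500, alpha = 0.05,
                                min_followers = 5L) {
  blocks <- partition_blocks(recording, block_size, active_min)
  mats <- lapply(blocks, function(b)
    extract_connections(compute_cfp(b, tau_bin_ms, tau_max_ms),
                        alpha = alpha, min_followers = min_followers))
  summary <- data.frame(
    block = vapply(mats, `[[`, numeric(1), "block_index"),
    mid_h = vapply(mats, `[[`, numeric(1), "mid_h"),
    phase = vapply(mats, function(m) m$phase %||% NA_character_, character(1)),
    n_connections = vapply(mats, `[[`, numeric(1), "N")
  )
  list(matrices = mats, summary = summary)
}

utils::globalVariables(c("bin", "count", "N"))
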