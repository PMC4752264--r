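#' Write / read the spike table of a recording as CSV
#'
#' The interchange schema is one row per spike: `time_s`, `electrode`,
#' and, when present, the ground-truth `unit` and `evoked` columns.
#' Waveform cutouts travel in a separate wide CSV (96 sample columns)
#' aligned row-by-row with the spike table.
#'
#' @param recording an `mea_recording`
#' @param path output CSV path
#' @param waveform_path optional path for the cutout matrix
#' @return invisibly, the path written
#' @export
write_spike_table <- function(recording, path, waveform_path = NULL) {
  utils::write.csv(recording$spikes, path, row.names = FALSE)
  if (!is.null(waveform_path)) {
    if (is.null(recording$waveforms)) stop("recording has no waveforms")
    utils::write.csv(as.data.frame(recording$waveforms), waveform_path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_spike_table
#' @param n_electrodes array size of the recording being read
#' @param duration_h recording duration (h); defaults to the last spike
#'   time rounded up to the next minute
#' @param timeline optional [phase_timeline()] to attach
#' @export
read_spike_table <- function(path, n_electrodes = 60L, duration_h = NULL,
                             timeline = NULL, waveform_path = NULL) {
  sp <- utils::read.csv(path)
  stopifnot(all(c("time_s", "electrode") %in% names(sp)))
  if (is.null(sp$unit)) sp$unit <- NA_integer_
  if (is.null(sp$evoked)) sp$evoked <- FALSE
  if (is.null(duration_h))
    duration_h <- ceiling(max(sp$time_s) / 60) / 60
  W <- if (!is.null(waveform_path))
    as.matrix(utils::read.csv(waveform_path)) else NULL
  rec <- new_recording(sp, ground_truth = NULL, protocol = NULL,
                       duration_h = duration_h, waveforms = W)
  rec$n_electrodes <- as.integer(n_electrodes)
  rec$timeline <- timeline
  rec
}

#' Export a block connectivity series as a long-format CSV
#'
#' One row per nonzero connection per block: `block`, `mid_h`, `phase`,
#' `i`, `j`, `S`, `T_ms` (and `S_norm` when strengths have been
#' baseline-normalized).
#'
#' @param matrices list of `connectivity_matrix` objects
#' @param path output CSV path
#' @return invisibly, the path
#' @export
write_connectivity_csv <- function(matrices, path) {
  rows <- lapply(matrices, function(m) {
    nz <- which(m$S != 0, arr.ind = TRUE)
    if (!nrow(nz)) return(NULL)
    d <- data.frame(block = m$block_index, mid_h = m$mid_h,
                    phase = m$phase %||% NA_character_,
                    i = nz[, 1], j = nz[, 2],
                    S = m$S[nz], T_ms = m$T_ms[nz])
    if (!is.null(m$S_norm)) d$S_norm <- m$S_norm[nz]
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
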