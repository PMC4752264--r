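`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Enforce a per-unit refractory period on a spike table
#'
#' Drops any spike that follows the previously retained spike of the same
#' unit by less than `refractory_s` (greedy, earliest-spike-wins). Used by
#' the generator so that synthetic single-unit trains never violate the
#' 1-ms refractory bookkeeping the single-neuron screening relies on.
#'
#' @param times numeric vector of spike times (s)
#' @param units integer vector of unit ids, same length
#' @param refractory_s refractory period in seconds (default 1 ms)
#' @return logical vector aligned with `times`: TRUE for spikes to keep
#' @keywords internal
refractory_keep <- function(times, units, refractory_s = 1e-3) {
  n <- length(times)
  if (n == 0L) return(logical(0))
  ord <- order(units, times)
  u_ord <- units[ord]
  t_ord <- times[ord]
  alive <- rep(TRUE, n)
  repeat {
    idx <- which(alive)
    t_a <- t_ord[idx]
    gap_ok <- c(TRUE, t_a[-1] - t_a[-length(t_a)] >= refractory_s)
    first_of_unit <- c(TRUE, u_ord[idx][-1] != u_ord[idx][-length(idx)])
    ok <- gap_ok | first_of_unit
    if (all(ok)) break
    # drop the first offender in each violating run, then re-check
    alive[idx[!ok & c(TRUE, ok[-length(ok)])]] <- FALSE
  }
  keep <- logical(n)
  keep[ord] <- alive
  keep
}
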