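#' Robust baseline noise estimate for an LFP trace
#'
#' The baseline noise level is estimated as 1.4826 times the median absolute
#' deviation of the full trace, a robust scale estimate that is insensitive
#' to epileptiform events occupying a minority of samples (the estimator's
#' breakdown point is far above the event occupancy seen in these
#' recordings).
#'
#' @param trace An `lfp_trace` with at least 1000 samples.
#' @return Noise SD in microvolts; 0 for a constant trace.
#' @examples
#' tr <- new_lfp_trace(seq(0, 10, by = 0.001), rnorm(10001))
#' estimate_noise(tr)
#' @export
estimate_noise <- function(trace) {
  validate_lfp(trace)
  if (nrow(trace) < 1000L) {
    stop("need at least 1000 samples to estimate baseline noise",
         call. = FALSE)
  }
  stats::mad(trace$amplitude_uv)
}

#' Detect epileptiform events in an LFP trace
#'
#' Implements the electrographic event rule: supra-threshold excursions
#' beyond `noise_multiple` times the estimated baseline noise (upward or
#' downward when `bidirectional`) are grouped into one event when separated
#' by less than `spike_merge_gap` ms; a group qualifies as an epileptiform
#' event only if it is multispike (at least two excursions) and its extent,
#' first to last supra-threshold sample, is strictly greater than
#' `min_duration` ms. Both gates are strict inequalities. An excursion must
#' itself be sustained for at least `min_excursion` ms (at least two
#' consecutive samples at typical rates), which rejects the single-sample
#' chance crossings of baseline noise. Because the threshold scales with the
#' estimated noise, detection is invariant to rescaling the whole trace.
#'
#' @param trace An `lfp_trace`.
#' @param cfg An [event_config()].
#' @return A data frame of class `event_table`, one row per event, sorted by
#'   start: `start_s`, `end_s`, `duration_ms`, `peak_uv`,
#'   `peak_noise_multiple`, `n_spikes`, `polarity` ("up", "down", "mixed").
#' @examples
#' amp <- rnorm(600001)
#' amp <- inject_polyspike(amp, 1000, at = 100, duration = 800,
#'                         amplitude = 5, noise_sd = 1)
#' tr <- new_lfp_trace(seq(0, 600, by = 0.001), amp)
#' detect_events(tr)
#' @export
detect_events <- function(trace, cfg = event_config()) {
  stopifnot(inherits(cfg, "event_config"))
  validate_lfp(trace)
  sigma <- estimate_noise(trace)
  if (sigma <= 0) {
    stop("degenerate trace: baseline noise estimate is zero", call. = FALSE)
  }
  x <- trace$amplitude_uv
  tt <- trace$time_s
  thr <- cfg$noise_multiple * sigma
  supra_up <- x > thr
  supra_dn <- x < -thr
  supra <- if (cfg$bidirectional) supra_up | supra_dn else supra_up

  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), peak_uv = numeric(0),
                      peak_noise_multiple = numeric(0),
                      n_spikes = integer(0), polarity = character(0))
  class(empty) <- c("event_table", "data.frame")
  if (!any(supra)) return(empty)

  r <- rle(supra)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values
  run_start <- run_start[keep]
  run_end <- run_end[keep]
  # debounce: an excursion must be sustained, not a one-sample noise blip
  sustained <- (tt[run_end] - tt[run_start]) * 1000 >= cfg$min_excursion
  run_start <- run_start[sustained]
  run_end <- run_end[sustained]
  if (length(run_start) == 0L) return(empty)

  # merge excursions separated by less than the merge gap
  gap_s <- cfg$spike_merge_gap / 1000
  if (length(run_start) > 1L) {
    gap <- tt[run_start[-1L]] - tt[run_end[-length(run_end)]]
    new_group <- c(TRUE, gap >= gap_s)
  } else {
    new_group <- TRUE
  }
  grp <- cumsum(new_group)
  g_start <- tapply(run_start, grp, function(i) i[1L])
  g_end <- tapply(run_end, grp, function(i) i[length(i)])
  g_n <- tabulate(grp)

  start_s <- tt[g_start]
  end_s <- tt[g_end]
  dur_ms <- (end_s - start_s) * 1000
  ok <- g_n >= 2L & dur_ms > cfg$min_duration
  if (!any(ok)) return(empty)

  idx <- which(ok)
  peak <- numeric(length(idx))
  pol <- character(length(idx))
  for (j in seq_along(idx)) {
    seg <- g_start[idx[j]]:g_end[idx[j]]
    seg_x <- x[seg]
    peak[j] <- max(abs(seg_x))
    has_up <- any(seg_x > thr)
    has_dn <- any(seg_x < -thr)
    pol[j] <- if (has_up && has_dn) "mixed" else if (has_up) "up" else "down"
  }
  ev <- data.frame(start_s = start_s[idx], end_s = end_s[idx],
                   duration_ms = dur_ms[idx], peak_uv = peak,
                   peak_noise_multiple = peak / sigma,
                   n_spikes = as.integer(g_n[idx]), polarity = pol)
  ev <- ev[order(ev$start_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Event count normalized to a reference epoch
#'
#' @param events An `event_table` from [detect_events()].
#' @param recorded Duration actually recorded, s.
#' @param epoch Reference epoch length, s (default 600, the 10-min epoch).
#' @return Events per epoch (count rescaled when `recorded != epoch`).
#' @examples
#' epoch_event_count(data.frame(start_s = 1:12), recorded = 600)
#' @export
epoch_event_count <- function(events, recorded = 600, epoch = 600) {
  stopifnot(recorded > 0, epoch > 0)
  nrow(events) * epoch / recorded
}

#' Electrographic suppression call for a treated fish or compound
#'
#' Compares the treated epileptiform event count per epoch with the
#' untreated mutant reference level. A compound is called suppressed when
#' the fractional reduction reaches `min_reduction` (default 0.9, a declared
#' convention for "reduced to control levels"); the raw counts are reported
#' for judgment.
#'
#' @param treated Events per epoch under treatment.
#' @param mutant_reference Events per epoch in untreated mutants; must be
#'   positive.
#' @param min_reduction Reduction fraction required for a suppression call.
#' @return An object of class `suppression_call`: list with
#'   `treated_count`, `reference_count`, `reduction_fraction`, `suppressed`.
#' @examples
#' suppression_call(2, 20)   # reduction 0.9 -> suppressed
#' @export
suppression_call <- function(treated, mutant_reference, min_reduction = 0.9) {
  stopifnot(treated >= 0, min_reduction >= 0, min_reduction <= 1)
  if (!is.numeric(mutant_reference) || mutant_reference <= 0) {
    stop("`mutant_reference` must be a positive event count", call. = FALSE)
  }
  red <- 1 - treated / mutant_reference
  structure(list(treated_count = treated,
                 reference_count = mutant_reference,
                 reduction_fraction = red,
                 suppressed = red >= min_reduction),
            class = "suppression_call")
}

#' @export
print.suppression_call <- function(x, ...) {
  cat(sprintf("Suppression call: %s (%.3g vs %.3g events/epoch, %.0f%% reduction)\n",
              if (x$suppressed) "SUPPRESSED" else "not suppressed",
              x$treated_count, x$reference_count,
              100 * x$reduction_fraction))
  invisible(x)
}
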