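#' Construct an LFP trace object
#'
#' A local field potential trace: a data frame with columns `time_s` and
#' `amplitude_uv`, sampled at a constant rate recoverable from the
#' timestamps.
#'
#' @param time_s Numeric timestamps, s, strictly increasing.
#' @param amplitude_uv Field potential, microvolts.
#' @param fish_id Optional fish identifier stored as an attribute.
#' @return A data frame of class `lfp_trace`.
#' @export
new_lfp_trace <- function(time_s, amplitude_uv, fish_id = NA_character_) {
  stopifnot(length(time_s) == length(amplitude_uv))
  tr <- data.frame(time_s = time_s, amplitude_uv = amplitude_uv)
  attr(tr, "fish_id") <- fish_id
  class(tr) <- c("lfp_trace", "data.frame")
  validate_lfp(tr)
  tr
}

validate_lfp <- function(trace) {
  if (!is.data.frame(trace) ||
      !all(c("time_s", "amplitude_uv") %in% names(trace))) {
    stop("LFP trace must have columns time_s, amplitude_uv", call. = FALSE)
  }
  if (nrow(trace) < 2L) {
    stop("LFP trace must contain at least two samples", call. = FALSE)
  }
  if (any(diff(trace$time_s) <= 0)) {
    stop("LFP timestamps must be strictly increasing", call. = FALSE)
  }
  invisible(trace)
}

lfp_rate <- function(trace) {
  1 / stats::median(diff(trace$time_s))
}

# One biphasic spike: a full sine cycle (up lobe then down lobe, or
# inverted), windowed to `width` seconds, peak amplitude `amp`.
spike_waveform <- function(t_rel, width, amp, sign = 1) {
  inside <- t_rel >= 0 & t_rel <= width
  w <- numeric(length(t_rel))
  w[inside] <- sign * amp * sin(2 * pi * t_rel[inside] / width)
  w
}

# Lead time from spike onset to the crossing of `threshold_multiple` x
# noise_sd for a spike of `amp_multiple` x noise_sd. Used to align injected
# deflection extents with detector crossing times.
spike_crossing_lead <- function(width, amp_multiple, threshold_multiple = 3) {
  (width / 2) * asin(threshold_multiple / amp_multiple) / pi
}

#' Inject a polyspike deflection into an amplitude vector
#'
#' Adds a train of biphasic spikes so that the first and last crossings of
#' the `threshold_multiple * noise_sd` level occur at `at` and
#' `at + duration / 1000` (up to sampling resolution). Spike spacing is kept
#' below `max_gap` so a detector with that merge gap groups the train into a
#' single event. Used by the generator and directly in detector boundary
#' experiments.
#'
#' @param amplitude_uv Numeric amplitude vector to modify.
#' @param rate Sampling rate, Hz.
#' @param at Event start time, s.
#' @param duration Event extent, ms.
#' @param amplitude Spike peak amplitude, microvolts.
#' @param noise_sd Baseline noise SD used for crossing alignment,
#'   microvolts.
#' @param threshold_multiple Detection threshold multiple to align to; set
#'   to 0 (or use an `amplitude` at or below the threshold) to place spikes
#'   without crossing alignment, e.g. in amplitude-bisection experiments.
#' @param spike_width Spike width, ms.
#' @param n_spikes Minimum number of spikes; more are inserted if needed to
#'   keep gaps below `max_gap`.
#' @param max_gap Maximum within-train spike spacing, ms.
#' @return The modified amplitude vector.
#' @export
inject_polyspike <- function(amplitude_uv, rate, at, duration, amplitude,
                             noise_sd, threshold_multiple = 3,
                             spike_width = 50, n_spikes = 2, max_gap = 150) {
  stopifnot(duration > 0, amplitude > 0)
  width <- spike_width / 1000
  lead <- if (threshold_multiple > 0 &&
              amplitude > threshold_multiple * noise_sd) {
    spike_crossing_lead(width, amplitude / noise_sd, threshold_multiple)
  } else 0
  # place spike onsets so first/last crossings sit at the extent endpoints
  first_on <- at - lead
  last_on <- at + duration / 1000 - (width - lead)
  span <- last_on - first_on
  k <- max(n_spikes, ceiling(span / (max_gap / 1000)) + 1L, 2L)
  onsets <- seq(first_on, last_on, length.out = k)
  n <- length(amplitude_uv)
  tt <- (seq_len(n) - 1L) / rate
  sgn <- rep_len(c(1, -1), k)      # alternating polarity within the train
  for (i in seq_len(k)) {
    j0 <- max(1L, floor(onsets[i] * rate) + 1L)
    j1 <- min(n, ceiling((onsets[i] + width) * rate) + 1L)
    if (j0 > j1) next
    idx <- j0:j1
    amplitude_uv[idx] <- amplitude_uv[idx] +
      spike_waveform(tt[idx] - onsets[i], width, amplitude, sgn[i])
  }
  amplitude_uv
}

#' Simulate a local field potential trace with ground-truth events
#'
#' Gaussian baseline noise with injected polyspike epileptiform events
#' (amplitude above 3x noise, extent above 500 ms by construction) and
#' optional brief interictal spikes that never qualify. Event count per
#' trace is Poisson with mean `event_rate * duration / 60`; event extents
#' are placed uniformly without overlap, separated by at least 600 ms so
#' that distinct events are never merged by the default detector.
#'
#' @param params An [lfp_params()] object.
#' @param duration Trace length, s.
#' @param rate Sampling rate, Hz; at least 200 Hz to resolve spikes.
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return A list with elements `trace` (an `lfp_trace`) and `ground_truth`
#'   (data frame `start_s`, `end_s`, `duration_ms`, `n_spikes` of injected
#'   qualifying events only).
#' @examples
#' sim <- simulate_lfp(lfp_params(event_rate = 3), duration = 60, seed = 1)
#' nrow(sim$ground_truth)
#' @export
simulate_lfp <- function(params, duration = 600, rate = 1000, seed = NULL) {
  stopifnot(inherits(params, "lfp_params"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (!is.numeric(rate) || rate < 200) {
    stop("`rate` must be at least 200 Hz to resolve spikes", call. = FALSE)
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_lfp(params, duration, rate)))
  }

  n <- as.integer(round(duration * rate)) + 1L
  tt <- (seq_len(n) - 1L) / rate
  amp <- stats::rnorm(n, 0, params$noise_sd)

  sep <- 0.6   # s between placed features; > default 200 ms merge gap
  truth <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), n_spikes = integer(0))

  k <- if (params$event_rate > 0) {
    stats::rpois(1, params$event_rate * duration / 60)
  } else 0L
  starts <- numeric(0)
  durs <- numeric(0)
  if (k > 0L) {
    durs <- stats::runif(k, params$event_duration_range[1],
                         params$event_duration_range[2]) / 1000
    if (sum(durs) + (k + 1) * sep >= duration) {
      stop("event rate/durations leave no room for non-overlapping events",
           call. = FALSE)
    }
    # non-overlapping placement preserving the Poisson count: distribute
    # the free time among k + 1 gaps via uniform spacings
    free <- duration - sum(durs) - (k + 1) * sep
    gaps <- diff(c(0, sort(stats::runif(k)), 1)) * free
    starts <- cumsum(gaps[seq_len(k)] + sep) +
      c(0, cumsum(durs))[seq_len(k)]
    nsp <- integer(k)
    for (i in seq_len(k)) {
      want <- sample(params$spikes_per_event_range[1]:
                       params$spikes_per_event_range[2], 1)
      a <- params$event_amplitude_multiple * params$noise_sd *
        stats::runif(1, 1.0, 1.3)
      amp <- inject_polyspike(amp, rate, starts[i], durs[i] * 1000, a,
                              params$noise_sd, n_spikes = want)
      nsp[i] <- want
    }
    truth <- data.frame(start_s = starts, end_s = starts + durs,
                        duration_ms = durs * 1000, n_spikes = nsp)
  }

  m <- if (params$interictal_spike_rate > 0) {
    stats::rpois(1, params$interictal_spike_rate * duration / 60)
  } else 0L
  if (m > 0L) {
    width <- params$spike_width / 1000
    placed <- numeric(0)
    cand <- stats::runif(4L * m, 0, duration - width)
    for (tc in cand) {
      if (length(placed) >= m) break
      clear_events <- k == 0L ||
        all(tc + width < starts - sep | tc > starts + durs + sep)
      clear_spikes <- length(placed) == 0L || all(abs(tc - placed) > sep)
      if (clear_events && clear_spikes) {
        a <- params$event_amplitude_multiple * params$noise_sd
        j0 <- max(1L, floor(tc * rate) + 1L)
        j1 <- min(n, ceiling((tc + width) * rate) + 1L)
        idx <- j0:j1
        amp[idx] <- amp[idx] +
          spike_waveform(tt[idx] - tc, width, a, sample(c(-1, 1), 1))
        placed <- c(placed, tc)
      }
    }
  }

  truth <- truth[order(truth$start_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(trace = new_lfp_trace(tt, amp), ground_truth = truth)
}
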