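# Shared fixture builders for the test suite.

# Per-fish trial table with uniform values, overridable per column.
make_fish <- function(n = 6, baseline = 10, treatment = 5, stage = 0L,
                      baseline_stage = NA_integer_, heartbeat = TRUE,
                      stimulus = TRUE) {
  data.frame(fish_id = sprintf("f%d", seq_len(n)),
             baseline_velocity = rep_len(baseline, n),
             treatment_velocity = rep_len(treatment, n),
             stage = rep_len(as.integer(stage), n),
             baseline_stage = rep_len(as.integer(baseline_stage), n),
             heartbeat = rep_len(heartbeat, n),
             stimulus_response = rep_len(stimulus, n),
             stringsAsFactors = FALSE)
}

# Gaussian-noise LFP trace with optional injected polyspike deflections.
# bursts: data frame with columns at (s), duration (ms), amplitude (xsigma).
noise_trace <- function(seed, duration = 600, rate = 1000, sd = 1,
                        bursts = NULL, quiet_window = NULL) {
  amp <- withr::with_seed(seed, stats::rnorm(duration * rate + 1, 0, sd))
  if (!is.null(quiet_window)) {
    idx <- seq(floor(quiet_window[1] * rate) + 1,
               ceiling(quiet_window[2] * rate) + 1)
    amp[idx] <- 0
  }
  if (!is.null(bursts)) {
    for (i in seq_len(nrow(bursts))) {
      amp <- inject_polyspike(amp, rate, at = bursts$at[i],
                              duration = bursts$duration[i],
                              amplitude = bursts$amplitude[i] * sd,
                              noise_sd = sd)
    }
  }
  new_lfp_trace(seq(0, duration, by = 1 / rate), amp)
}

# 600 s quiescent trajectory with one constant-velocity bout (t6-style).
bout_trajectory <- function(bout_speed, bout_s = 1, rate = 25,
                            total_s = 600) {
  n <- total_s * rate
  speeds <- rep(0, n)
  i0 <- (total_s / 2) * rate
  speeds[i0:(i0 + bout_s * rate - 1)] <- bout_speed
  trajectory_from_speeds(speeds, rate)
}
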