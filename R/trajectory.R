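#' Construct a trajectory object
#'
#' A trajectory is a positional time series for one fish in one well:
#' a data frame with columns `time_s`, `x_mm`, `y_mm` and strictly
#' increasing timestamps.
#'
#' @param time_s Numeric vector of timestamps, s, strictly increasing.
#' @param x_mm,y_mm Numeric coordinate vectors, mm.
#' @param fish_id Optional fish identifier stored as an attribute.
#' @return A data frame of class `trajectory`.
#' @export
new_trajectory <- function(time_s, x_mm, y_mm, fish_id = NA_character_) {
  stopifnot(length(time_s) == length(x_mm), length(x_mm) == length(y_mm))
  tr <- data.frame(time_s = time_s, x_mm = x_mm, y_mm = y_mm)
  attr(tr, "fish_id") <- fish_id
  class(tr) <- c("trajectory", "data.frame")
  validate_trajectory(tr)
  tr
}

validate_trajectory <- function(traj) {
  if (!is.data.frame(traj) ||
      !all(c("time_s", "x_mm", "y_mm") %in% names(traj))) {
    stop("trajectory must have columns time_s, x_mm, y_mm", call. = FALSE)
  }
  if (nrow(traj) < 2L) {
    stop("trajectory must contain at least two samples", call. = FALSE)
  }
  dt <- diff(traj$time_s)
  if (any(dt <= 0)) {
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  }
  invisible(traj)
}

#' Build a straight-line trajectory from an instantaneous speed profile
#'
#' Convenience constructor for controlled experiments: the fish moves along
#' the x axis with the given per-frame speed, so the velocity series of the
#' result reproduces `speeds` exactly.
#'
#' @param speeds Per-frame speeds, mm/s (one per inter-sample step).
#' @param rate Sampling rate, Hz.
#' @return A `trajectory` with `length(speeds) + 1` samples.
#' @examples
#' tr <- trajectory_from_speeds(c(0, 0, 10, 10, 0), rate = 25)
#' velocity_series(tr)$velocity_mm_s
#' @export
trajectory_from_speeds <- function(speeds, rate = 25) {
  stopifnot(is.numeric(speeds), length(speeds) >= 1, all(speeds >= 0),
            rate > 0)
  n <- length(speeds)
  time_s <- seq(0, n) / rate
  x <- c(0, cumsum(speeds / rate))
  new_trajectory(time_s, x, rep(0, n + 1L))
}

# Side length of the square arena approximating one well of a 96-well
# microplate (mm). Positions are confined to [-half, half]^2.
.arena_side <- 6.4

# Effective log-scale SD of the intrinsic (bout/burst counting) variability
# of mean velocity at 600 s, 25 Hz under default mutant parameters. This is
# a calibration constant fixed once by simulation: it is slightly below the
# raw sd(log v) of replicate recordings (0.088) because the intrinsic
# velocity distribution is not exactly lognormal, and is chosen so that the
# default trial_variability_sd target of 21.8% is reproduced.
.intrinsic_log_sd <- 0.0772

# Lognormal sigma of the per-recording activity factor needed so that the
# percent change between two recordings has the target sample SD, after
# accounting for the intrinsic counting variability above.
trial_sigma <- function(target_sd_percent) {
  t2 <- (target_sd_percent / 100)^2
  s_tot2 <- log((1 + sqrt(1 + 4 * t2)) / 2)
  s2 <- (s_tot2 - 2 * .intrinsic_log_sd^2) / 2
  sqrt(max(s2, 0))
}

# Fold coordinates into [-half, half] by mirror reflection, preserving
# per-step displacement except on the rare frames that span a crease.
fold_coord <- function(z, half) {
  2 * half - abs((z + half) %% (4 * half) - 2 * half) - half
}

#' Apply a drug effect to behavior parameters
#'
#' Scales swim speeds by the effect's `velocity_scale` and the Stage III
#' burst rate by `burst_rate_scale`; a killing effect zeroes all movement.
#' The mutant burst-speed floor is deliberately not re-validated: a sedative
#' may legitimately slow convulsive bursts below 20 mm/s.
#'
#' @param params A [larva_params()].
#' @param effect A [drug_effect()].
#' @return A modified `larva_params` object.
#' @export
apply_drug_effect <- function(params, effect) {
  stopifnot(inherits(params, "larva_params"), inherits(effect, "drug_effect"))
  p <- unclass(params)
  vs <- if (effect$kills) 0 else effect$velocity_scale
  p$quiescent_speed_mean <- p$quiescent_speed_mean * vs
  p$bout_speed_mean <- p$bout_speed_mean * vs
  p$stage3_burst_speed <- p$stage3_burst_speed * vs
  p$stage3_burst_rate <- p$stage3_burst_rate *
    (if (effect$kills) 0 else effect$burst_rate_scale)
  class(p) <- "larva_params"
  p
}

#' Simulate one larval swim trajectory
#'
#' Generates a positional time series from a two-state renewal model:
#' quiescent drift interrupted by brief swim bouts (Poisson onsets,
#' exponential durations), with Stage III convulsive bursts superimposed at
#' their own Poisson rate. Burst movement is rendered as rapid near-circular
#' swimming so that instantaneous velocity stays at the burst speed while the
#' fish remains inside the well; slower movement is a heading-persistent
#' random walk reflected at the well wall. A per-recording lognormal activity
#' factor scales all speeds and reproduces the trial-to-trial variability of
#' untreated controls.
#'
#' @param params A [larva_params()] object.
#' @param duration Epoch length, s.
#' @param rate Sampling rate, Hz.
#' @param seed Optional integer seed; identical `(params, seed)` give
#'   bitwise-identical output. With `seed = NULL` the current RNG stream is
#'   used (so that plate- and screen-level simulations are reproducible from
#'   a single top-level seed).
#' @return A `trajectory` (see [new_trajectory()]).
#' @examples
#' tr <- simulate_trajectory(larva_params("mutant"), duration = 60, seed = 1)
#' max(velocity_series(tr)$velocity_mm_s)
#' @export
simulate_trajectory <- function(params, duration = 600, rate = 25,
                                seed = NULL) {
  stopifnot(inherits(params, "larva_params"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (!is.numeric(rate) || rate <= 0) {
    stop("`rate` must be positive", call. = FALSE)
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
                            simulate_trajectory(params, duration, rate)))
  }

  dt <- 1 / rate
  nstep <- max(1L, as.integer(round(duration * rate)))
  time_s <- seq(0L, nstep) * dt
  half <- .arena_side / 2

  # per-recording activity factor
  act <- stats::rlnorm(1, 0, trial_sigma(params$trial_variability_sd))

  # per-step speeds: quiescent drift, overridden by bouts, then bursts
  mid <- (seq_len(nstep) - 0.5) * dt
  speed <- stats::rexp(nstep, 1) * params$quiescent_speed_mean
  speed <- overlay_intervals(
    speed, mid,
    rate_per_min = params$bout_rate, duration = duration,
    dur_fun = function(k) stats::rexp(k, 1 / params$bout_duration_mean),
    speed_fun = function(k) {
      pmax(stats::rnorm(k, params$bout_speed_mean,
                        0.2 * params$bout_speed_mean), 0)
    }
  )
  burst <- overlay_intervals(
    rep(NA_real_, nstep), mid,
    rate_per_min = params$stage3_burst_rate, duration = duration,
    dur_fun = function(k) stats::runif(k, params$burst_duration_range[1],
                                       params$burst_duration_range[2]),
    speed_fun = function(k) {
      params$stage3_burst_speed * stats::runif(k, 1.0, 1.15)
    }
  )
  in_burst <- !is.na(burst)
  speed[in_burst] <- burst[in_burst]
  speed <- speed * act

  pos <- integrate_path(speed, in_burst, dt, half)
  x <- pos$x + stats::rnorm(nstep + 1L, 0, params$positional_noise_sd)
  y <- pos$y + stats::rnorm(nstep + 1L, 0, params$positional_noise_sd)
  x <- pmin(pmax(x, -half), half)
  y <- pmin(pmax(y, -half), half)
  new_trajectory(time_s, x, y)
}

# Overlay Poisson-process intervals onto a per-step value vector. Each event
# has an onset uniform over the epoch, a duration from dur_fun and a value
# from speed_fun; later onsets win where events overlap.
overlay_intervals <- function(base, mid, rate_per_min, duration, dur_fun,
                              speed_fun) {
  if (rate_per_min <= 0) return(base)
  k <- stats::rpois(1, rate_per_min * duration / 60)
  if (k == 0L) return(base)
  onset <- sort(stats::runif(k, 0, duration))
  dur <- dur_fun(k)
  val <- speed_fun(k)
  idx <- findInterval(mid, onset)          # latest onset at or before mid
  covered <- idx > 0L
  covered[covered] <- mid[covered] <= onset[idx[covered]] + dur[idx[covered]]
  base[covered] <- val[idx[covered]]
  base
}

# Integrate per-step speeds into confined positions. Non-burst segments are
# a heading random walk folded back into the arena; burst segments trace a
# circle kept fully inside the arena so that frame-to-frame displacement
# remains at the burst speed.
integrate_path <- function(speed, in_burst, dt, half) {
  nstep <- length(speed)
  heading <- cumsum(stats::rnorm(nstep, 0, 0.8)) + stats::runif(1, 0, 2 * pi)
  r_circ <- 2                       # burst swimming-circle radius, mm
  margin <- half - r_circ - 0.1     # max |center| keeping circle inside

  x <- numeric(nstep + 1L)
  y <- numeric(nstep + 1L)
  # segment boundaries where burst state changes
  change <- c(TRUE, in_burst[-1L] != in_burst[-nstep])
  seg_start <- which(change)
  seg_end <- c(seg_start[-1L] - 1L, nstep)
  cx <- 0
  cy <- 0
  for (s in seq_along(seg_start)) {
    i0 <- seg_start[s]
    i1 <- seg_end[s]
    idx <- i0:i1
    if (in_burst[i0]) {
      ccx <- min(max(cx, -margin), margin)
      ccy <- min(max(cy, -margin), margin)
      phi0 <- atan2(cy - ccy, cx - ccx)
      dir <- sample(c(-1, 1), 1)
      phi <- phi0 + dir * cumsum(speed[idx] * dt) / r_circ
      px <- ccx + r_circ * cos(phi)
      py <- ccy + r_circ * sin(phi)
    } else {
      dx <- speed[idx] * dt * cos(heading[idx])
      dy <- speed[idx] * dt * sin(heading[idx])
      px <- fold_coord(cx + cumsum(dx), half)
      py <- fold_coord(cy + cumsum(dy), half)
    }
    x[idx + 1L] <- px
    y[idx + 1L] <- py
    cx <- px[length(px)]
    cy <- py[length(py)]
  }
  # first sample is the pre-step position of the first segment
  if (in_burst[1L]) {
    x[1L] <- x[2L]
    y[1L] <- y[2L]
  }
  list(x = x, y = y)
}
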