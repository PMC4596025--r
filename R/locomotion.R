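#' Instantaneous velocity series of a trajectory
#'
#' Frame-to-frame Euclidean displacement divided by the inter-sample
#' interval. No smoothing is applied by default; an optional centered
#' moving average is available because tracker post-processing settings
#' vary between rigs.
#'
#' @param traj A `trajectory`.
#' @param smooth_frames Optional odd integer window for a centered moving
#'   average of the velocity series; `1` (default) disables smoothing.
#' @return A data frame with columns `time_s` (interval midpoints) and
#'   `velocity_mm_s`, one row per inter-sample step.
#' @examples
#' tr <- trajectory_from_speeds(rep(50, 10), rate = 25)
#' velocity_series(tr)$velocity_mm_s   # constant 50 mm/s
#' @export
velocity_series <- function(traj, smooth_frames = 1L) {
  validate_trajectory(traj)
  dt <- diff(traj$time_s)
  disp <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
  v <- disp / dt
  if (smooth_frames > 1L) {
    if (smooth_frames %% 2L == 0L) {
      stop("`smooth_frames` must be odd", call. = FALSE)
    }
    v <- as.numeric(stats::filter(v, rep(1 / smooth_frames, smooth_frames),
                                  sides = 2))
    v[is.na(v)] <- 0
  }
  data.frame(time_s = traj$time_s[-length(traj$time_s)] + dt / 2,
             velocity_mm_s = v)
}

#' Locomotion metrics for one recording epoch
#'
#' Distance traveled (mm), mean velocity (mm/s, defined as distance divided
#' by the epoch duration), maximum instantaneous velocity, and the fraction
#' of the epoch spent in active swimming (frames above
#' `active_speed_threshold`).
#'
#' @param traj A `trajectory` spanning the epoch.
#' @param active_speed_threshold Velocity above which a frame counts as
#'   active, mm/s.
#' @return An object of class `locomotion_metrics`: a list with fields
#'   `distance`, `mean_velocity`, `max_velocity`, `active_fraction`,
#'   `epoch_duration`.
#' @examples
#' tr <- trajectory_from_speeds(rep(10, 150), rate = 25)  # 6 s at 10 mm/s
#' locomotion_metrics(tr)$mean_velocity
#' @export
locomotion_metrics <- function(traj, active_speed_threshold = 2) {
  validate_trajectory(traj)
  dt <- diff(traj$time_s)
  disp <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
  v <- disp / dt
  epoch <- traj$time_s[length(traj$time_s)] - traj$time_s[1L]
  out <- list(distance = sum(disp),
              mean_velocity = sum(disp) / epoch,
              max_velocity = max(v),
              active_fraction = sum(dt[v > active_speed_threshold]) / epoch,
              epoch_duration = epoch)
  class(out) <- "locomotion_metrics"
  out
}

#' @export
print.locomotion_metrics <- function(x, ...) {
  cat(sprintf(paste0("Locomotion metrics: %.1f mm over %.0f s ",
                     "(mean %.2f mm/s, max %.1f mm/s, active %.1f%%)\n"),
              x$distance, x$epoch_duration, x$mean_velocity, x$max_velocity,
              100 * x$active_fraction))
  invisible(x)
}

#' Percent change in mean velocity between two recordings
#'
#' `100 * (treatment - baseline) / baseline` on mean velocity; negative
#' values indicate suppression of swim activity. Mean velocity is used
#' because velocity changes are the more sensitive readout of seizure
#' behavior; set `measure = "distance"` to use distance traveled instead
#' (the two coincide when epochs are equal).
#'
#' @param baseline,treatment `locomotion_metrics` for the two recordings of
#'   the same fish.
#' @param measure `"mean_velocity"` (default) or `"distance"`.
#' @return Percent change (a single number).
#' @examples
#' b <- list(mean_velocity = 10); class(b) <- "locomotion_metrics"
#' t <- list(mean_velocity = 5);  class(t) <- "locomotion_metrics"
#' percent_change(b, t)   # -50
#' @export
percent_change <- function(baseline, treatment,
                           measure = c("mean_velocity", "distance")) {
  measure <- match.arg(measure)
  b <- baseline[[measure]]
  t <- treatment[[measure]]
  if (is.null(b) || is.null(t)) {
    stop("both recordings must carry the requested measure", call. = FALSE)
  }
  if (b <= 0) {
    stop("baseline is zero; percent change undefined (exclude this fish)",
         call. = FALSE)
  }
  100 * (t - b) / b
}

#' Score a trajectory on the three-stage seizure scale
#'
#' Stage III requires a sustained run of instantaneous velocity at or above
#' the convulsion threshold (default 20 mm/s) lasting at least
#' `cfg$stage3_min_bout`. Otherwise the stage is assigned from the active
#' fraction: Stage 0 (no or very little swim activity), Stage I (brief
#' bouts), Stage II (sustained rapid swimming, the operationalization of
#' whirlpool-like circling).
#'
#' @param traj A `trajectory`.
#' @param cfg A [stage_config()].
#' @return Integer stage in `0:3`.
#' @examples
#' quiet <- trajectory_from_speeds(rep(0, 250), rate = 25)
#' score_stage(quiet)   # 0
#' burst <- trajectory_from_speeds(c(rep(0, 100), rep(25, 25), rep(0, 100)))
#' score_stage(burst)   # 3
#' @export
score_stage <- function(traj, cfg = stage_config()) {
  stopifnot(inherits(cfg, "stage_config"))
  validate_trajectory(traj)
  vs <- velocity_series(traj)
  dt <- diff(traj$time_s)
  supra <- vs$velocity_mm_s >= cfg$stage3_velocity_threshold
  if (any(supra)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (sum(dt[starts[j]:ends[j]]) >= cfg$stage3_min_bout) return(3L)
    }
  }
  m <- locomotion_metrics(traj,
                          active_speed_threshold = cfg$active_speed_threshold)
  if (m$active_fraction <= cfg$stage0_max_active_fraction) return(0L)
  if (m$active_fraction <= cfg$stage1_max_active_fraction) return(1L)
  2L
}
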