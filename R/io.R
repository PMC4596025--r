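#' Read and write trajectory files
#'
#' Trajectories are stored as CSV with header `time_s,x_mm,y_mm` and
#' strictly increasing time.
#'
#' @param path File path.
#' @param traj A `trajectory`.
#' @return `read_trajectory()` returns a `trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "x_mm", "y_mm") %in% names(d))) {
    stop("trajectory file must have header time_s,x_mm,y_mm", call. = FALSE)
  }
  new_trajectory(d$time_s, d$x_mm, d$y_mm)
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  validate_trajectory(traj)
  utils::write.csv(as.data.frame(traj)[c("time_s", "x_mm", "y_mm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write LFP trace files
#'
#' LFP traces are stored as CSV with header `time_s,amplitude_uv`; the
#' sample rate is recoverable from the timestamps.
#'
#' @param path File path.
#' @param trace An `lfp_trace`.
#' @return `read_lfp()` returns an `lfp_trace`; `write_lfp()` returns
#'   `path` invisibly.
#' @export
read_lfp <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_uv") %in% names(d))) {
    stop("LFP file must have header time_s,amplitude_uv", call. = FALSE)
  }
  new_lfp_trace(d$time_s, d$amplitude_uv)
}

#' @rdname read_lfp
#' @export
write_lfp <- function(trace, path) {
  validate_lfp(trace)
  utils::write.csv(as.data.frame(trace)[c("time_s", "amplitude_uv")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a plate manifest and its recordings to disk
#'
#' Writes every recording of a plate as trajectory CSVs plus a JSON
#' manifest mapping wells to compound, concentration, recording paths and
#' viability flags. The plate must have been simulated with
#' `keep_trajectories = TRUE`.
#'
#' @param plate A `plate_dataset` with recordings.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "plate_dataset"))
  if (is.null(plate$recordings)) {
    stop("plate was simulated without trajectories; nothing to write",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- plate$summary
  wells <- lapply(seq_len(nrow(s)), function(i) {
    fid <- s$fish_id[i]
    bp <- file.path(dir, paste0(fid, "_baseline.csv"))
    tp <- file.path(dir, paste0(fid, "_treatment.csv"))
    write_trajectory(plate$recordings[[fid]]$baseline, bp)
    write_trajectory(plate$recordings[[fid]]$treatment, tp)
    list(well_id = s$well_id[i], fish_id = fid,
         compound_id = s$compound_id[i],
         concentration_um = if (is.na(s$concentration_um[i])) NULL
                            else s$concentration_um[i],
         baseline_path = basename(bp), treatment_path = basename(tp),
         viability = list(heartbeat = s$heartbeat[i],
                          stimulus_response = s$stimulus_response[i]))
  })
  manifest <- list(plate_id = plate$plate_id, wells = wells)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a plate manifest
#'
#' @param path Path to a manifest JSON written by [write_plate()].
#' @return A list with `plate_id` and a `wells` data frame including
#'   viability flags and recording paths (relative to the manifest).
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  wells <- do.call(rbind, lapply(m$wells, function(w) {
    data.frame(well_id = w$well_id, fish_id = w$fish_id,
               compound_id = w$compound_id,
               concentration_um = if (length(w$concentration_um) != 1L ||
                                      identical(w$concentration_um, "NA"))
                 NA_real_ else as.numeric(w$concentration_um),
               baseline_path = w$baseline_path,
               treatment_path = w$treatment_path,
               heartbeat = isTRUE(w$viability$heartbeat),
               stimulus_response = isTRUE(w$viability$stimulus_response),
               stringsAsFactors = FALSE)
  }))
  list(plate_id = m$plate_id, wells = wells)
}

#' Per-fish locomotion metrics table for a plate
#'
#' @param plate A `plate_dataset`.
#' @return Data frame with one row per (fish, recording): `fish_id`,
#'   `recording` ("baseline"/"treatment"), `distance_mm`,
#'   `mean_velocity_mm_s`, `max_velocity_mm_s`, `stage`.
#' @export
metrics_table <- function(plate) {
  stopifnot(inherits(plate, "plate_dataset"))
  s <- plate$summary
  epoch <- plate$design$epoch_duration
  base <- data.frame(fish_id = s$fish_id, recording = "baseline",
                     distance_mm = s$baseline_velocity * epoch,
                     mean_velocity_mm_s = s$baseline_velocity,
                     max_velocity_mm_s = s$baseline_max_velocity,
                     stage = s$baseline_stage, stringsAsFactors = FALSE)
  trt <- data.frame(fish_id = s$fish_id, recording = "treatment",
                    distance_mm = s$treatment_velocity * epoch,
                    mean_velocity_mm_s = s$treatment_velocity,
                    max_velocity_mm_s = s$treatment_max_velocity,
                    stage = s$treatment_stage, stringsAsFactors = FALSE)
  out <- rbind(base, trt)
  out[order(out$fish_id, out$recording), ]
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the artifacts of a screen run
#'
#' @param res A `screen_run` from [run_screen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_artifacts <- function(res, dir) {
  stopifnot(inherits(res, "screen_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(res$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  write_tsv(res$compounds, file.path(dir, "compounds.tsv"))
  if (nrow(res$ephys) > 0) {
    write_tsv(res$ephys, file.path(dir, "ephys.tsv"))
  }
  hm <- heatmap_table(c(res$trials1, res$trials2))
  utils::write.csv(hm, file.path(dir, "heatmap.csv"), row.names = FALSE,
                   quote = FALSE)
  log <- list(seed = res$seed, threshold_percent = res$threshold,
              control_n = res$control_stats$n,
              control_sd_percent = res$control_stats$sd_percent_change,
              n_compounds = res$config$n_compounds,
              fish_fraction = res$config$criteria$fish_fraction,
              stage3_velocity_threshold =
                res$config$stage_cfg$stage3_velocity_threshold,
              noise_multiple = res$config$event_cfg$noise_multiple,
              min_duration_ms = res$config$event_cfg$min_duration,
              epoch_s = res$config$design$epoch_duration)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Classify every compound in a plate manifest from its recordings
#'
#' File-based entry to the first screening stage: reads the manifest and the
#' trajectory CSVs it references, computes locomotion metrics and seizure
#' stages, assembles per-compound trials and classifies them.
#'
#' @param manifest_path Path to a manifest JSON (see [write_plate()]).
#' @param criteria A [hit_criteria()].
#' @param stage_cfg A [stage_config()].
#' @param trial Trial index recorded in the classifications.
#' @return A list with `classifications` (list of `classification`),
#'   `table` (per-compound data frame: `compound_id`, `concentration_um`,
#'   `trial`, `n_fish`, `n_alive`, `mean_pct_change`, `n_stage01`,
#'   `n_stage3`, `label`) and `control_pairs` (data frame for
#'   [control_variability()]).
#' @export
classify_manifest <- function(manifest_path, criteria = hit_criteria(),
                              stage_cfg = stage_config(), trial = 1L) {
  m <- read_manifest(manifest_path)
  dir <- dirname(manifest_path)
  w <- m$wells
  w$baseline_velocity <- NA_real_
  w$treatment_velocity <- NA_real_
  w$baseline_stage <- NA_integer_
  w$stage <- NA_integer_
  for (i in seq_len(nrow(w))) {
    tb <- read_trajectory(file.path(dir, w$baseline_path[i]))
    tt <- read_trajectory(file.path(dir, w$treatment_path[i]))
    w$baseline_velocity[i] <- locomotion_metrics(
      tb, stage_cfg$active_speed_threshold)$mean_velocity
    w$treatment_velocity[i] <- locomotion_metrics(
      tt, stage_cfg$active_speed_threshold)$mean_velocity
    w$baseline_stage[i] <- score_stage(tb, stage_cfg)
    w$stage[i] <- score_stage(tt, stage_cfg)
  }
  ctrl <- w$compound_id == "CONTROL"
  cls <- lapply(split(w[!ctrl, ], w$compound_id[!ctrl]), function(d) {
    classify_compound(
      compound_trial(d$compound_id[1L],
                     d[c("fish_id", "baseline_velocity",
                         "treatment_velocity", "stage", "baseline_stage",
                         "heartbeat", "stimulus_response")],
                     concentration_um = d$concentration_um[1L],
                     trial = trial),
      criteria)
  })
  tab <- do.call(rbind, lapply(cls, function(x) {
    data.frame(compound_id = x$compound_id,
               concentration_um = x$concentration_um, trial = x$trial,
               n_fish = x$n_fish, n_alive = x$n_alive,
               mean_pct_change = x$mean_percent_change,
               n_stage01 = x$n_qualifying_stage, n_stage3 = x$n_stage3,
               label = x$label, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(classifications = cls, table = tab,
       control_pairs = data.frame(
         baseline_velocity = w$baseline_velocity[ctrl],
         second_velocity = w$treatment_velocity[ctrl]))
}
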