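#' Behavioral parameters for a simulated larva
#'
#' Describes the two-state (quiescent/bout) swim model with superimposed
#' Stage III convulsive bursts used by [simulate_trajectory()]. Mutant
#' defaults produce spontaneous high-velocity (>= 20 mm/s) bursts; wild-type
#' defaults produce none.
#'
#' @param genotype `"mutant"` or `"wildtype"`; selects the default set.
#' @param quiescent_speed_mean Mean drift speed between bouts, mm/s.
#' @param bout_rate Swim bout initiation rate, bouts/min.
#' @param bout_speed_mean Mean speed during an ordinary swim bout, mm/s.
#' @param bout_duration_mean Mean bout duration, s (exponential).
#' @param stage3_burst_rate Rate of convulsive Stage III bursts, bursts/min.
#'   Zero for wild type.
#' @param stage3_burst_speed Swim speed during a Stage III burst, mm/s. Must
#'   be at or above the conventional 20 mm/s convulsion threshold when
#'   `stage3_burst_rate > 0`.
#' @param burst_duration_range Length-2 numeric, min/max burst duration, s.
#' @param positional_noise_sd Tracking jitter added to each coordinate, mm.
#' @param trial_variability_sd Target sample SD (in percent) of the percent
#'   change in mean velocity between two consecutive untreated recordings of
#'   the same fish. Realized as a per-recording multiplicative lognormal
#'   activity factor; the default reproduces the 21.8% trial-to-trial
#'   variability observed in untreated mutant controls.
#' @return An object of class `larva_params`.
#' @examples
#' larva_params("mutant")
#' larva_params("wildtype")
#' @export
larva_params <- function(genotype = c("mutant", "wildtype"),
                         quiescent_speed_mean = NULL,
                         bout_rate = NULL,
                         bout_speed_mean = NULL,
                         bout_duration_mean = 0.3,
                         stage3_burst_rate = NULL,
                         stage3_burst_speed = NULL,
                         burst_duration_range = c(1.0, 2.5),
                         positional_noise_sd = 0.01,
                         trial_variability_sd = 21.8) {
  genotype <- match.arg(genotype)
  def <- if (genotype == "mutant") {
    list(quiescent_speed_mean = 0.5, bout_rate = 30, bout_speed_mean = 8,
         stage3_burst_rate = 6, stage3_burst_speed = 25)
  } else {
    list(quiescent_speed_mean = 0.3, bout_rate = 20, bout_speed_mean = 5,
         stage3_burst_rate = 0, stage3_burst_speed = 0)
  }
  p <- list(
    genotype = genotype,
    quiescent_speed_mean = quiescent_speed_mean %||% def$quiescent_speed_mean,
    bout_rate = bout_rate %||% def$bout_rate,
    bout_speed_mean = bout_speed_mean %||% def$bout_speed_mean,
    bout_duration_mean = bout_duration_mean,
    stage3_burst_rate = stage3_burst_rate %||% def$stage3_burst_rate,
    stage3_burst_speed = stage3_burst_speed %||% def$stage3_burst_speed,
    burst_duration_range = burst_duration_range,
    positional_noise_sd = positional_noise_sd,
    trial_variability_sd = trial_variability_sd
  )
  num <- c("quiescent_speed_mean", "bout_rate", "bout_speed_mean",
           "bout_duration_mean", "stage3_burst_rate", "stage3_burst_speed",
           "positional_noise_sd", "trial_variability_sd")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) ||
        p[[f]] < 0) {
      stop(sprintf("`%s` must be a single non-negative number", f),
           call. = FALSE)
    }
  }
  if (length(p$burst_duration_range) != 2L ||
      any(p$burst_duration_range <= 0) ||
      diff(p$burst_duration_range) < 0) {
    stop("`burst_duration_range` must be an increasing positive pair",
         call. = FALSE)
  }
  if (p$stage3_burst_rate > 0 && p$stage3_burst_speed < 20) {
    stop("`stage3_burst_speed` must be >= 20 mm/s when bursts are present",
         call. = FALSE)
  }
  structure(p, class = "larva_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drug effect applied to a simulated compound well
#'
#' Encodes how a compound perturbs swim behavior and electrographic activity.
#' The five classes mirror the outcome categories of the screen: true
#' suppressors, toxic compounds, proconvulsants, inert compounds, and
#' behavioral false positives that sedate swimming while leaving
#' electrographic discharges untouched.
#'
#' @param effect_class One of `"suppressive"`, `"toxic"`, `"proconvulsant"`,
#'   `"inert"`, `"behavioral_false_positive"`.
#' @param velocity_scale Multiplier applied to all swim speeds.
#' @param burst_rate_scale Multiplier on the Stage III burst rate.
#' @param lfp_event_rate_scale Multiplier on the electrographic
#'   epileptiform-event rate.
#' @param kills If `TRUE`, fish lose heartbeat and stimulus response and
#'   treatment movement is flattened.
#' @return An object of class `drug_effect`.
#' @examples
#' drug_effect("suppressive")
#' drug_effect("behavioral_false_positive")
#' @export
drug_effect <- function(effect_class = c("inert", "suppressive", "toxic",
                                         "proconvulsant",
                                         "behavioral_false_positive"),
                        velocity_scale = NULL,
                        burst_rate_scale = NULL,
                        lfp_event_rate_scale = NULL,
                        kills = NULL) {
  effect_class <- match.arg(effect_class)
  def <- switch(effect_class,
    inert = list(velocity_scale = 1, burst_rate_scale = 1,
                 lfp_event_rate_scale = 1, kills = FALSE),
    suppressive = list(velocity_scale = 0.3, burst_rate_scale = 0,
                       lfp_event_rate_scale = 0.05, kills = FALSE),
    toxic = list(velocity_scale = 0, burst_rate_scale = 0,
                 lfp_event_rate_scale = 0, kills = TRUE),
    proconvulsant = list(velocity_scale = 1.6, burst_rate_scale = 2,
                         lfp_event_rate_scale = 2, kills = FALSE),
    behavioral_false_positive = list(velocity_scale = 0.3,
                                     burst_rate_scale = 0,
                                     lfp_event_rate_scale = 1, kills = FALSE)
  )
  e <- list(
    effect_class = effect_class,
    velocity_scale = velocity_scale %||% def$velocity_scale,
    burst_rate_scale = burst_rate_scale %||% def$burst_rate_scale,
    lfp_event_rate_scale = lfp_event_rate_scale %||% def$lfp_event_rate_scale,
    kills = kills %||% def$kills
  )
  stopifnot(is.numeric(e$velocity_scale), e$velocity_scale >= 0,
            is.numeric(e$burst_rate_scale), e$burst_rate_scale >= 0,
            is.numeric(e$lfp_event_rate_scale), e$lfp_event_rate_scale >= 0,
            is.logical(e$kills), length(e$kills) == 1L)
  if (effect_class == "suppressive" &&
      (e$velocity_scale >= 1 || e$lfp_event_rate_scale >= 1)) {
    stop("suppressive effects must scale both velocity and LFP rate below 1",
         call. = FALSE)
  }
  if (effect_class == "behavioral_false_positive" &&
      (e$velocity_scale >= 1 || e$lfp_event_rate_scale != 1)) {
    stop(paste("behavioral false positives must scale velocity below 1 and",
               "leave the LFP event rate unchanged"), call. = FALSE)
  }
  if (effect_class == "toxic" && !e$kills) {
    stop("toxic effects must set `kills = TRUE`", call. = FALSE)
  }
  structure(e, class = "drug_effect")
}

#' Generator parameters for a synthetic LFP trace
#'
#' Parameters for [simulate_lfp()]. Qualifying epileptiform events are
#' polyspike trains whose amplitude exceeds 3x the baseline noise and whose
#' extent exceeds 500 ms; brief interictal spikes are single transients that
#' never qualify and exist to stress the duration and multispike gates of the
#' detector.
#'
#' @param noise_sd Baseline noise SD, microvolts.
#' @param event_rate Qualifying epileptiform event rate, events/min.
#' @param event_duration_range Length-2 numeric, min/max event extent, ms.
#'   Both must exceed 500 ms.
#' @param event_amplitude_multiple Spike peak amplitude as a multiple of
#'   `noise_sd`; must exceed 3.
#' @param spikes_per_event_range Length-2 integer, min/max spikes per event.
#'   Additional spikes are inserted if needed to keep within-event gaps below
#'   the detector's merge gap.
#' @param interictal_spike_rate Rate of isolated sub-500-ms spikes,
#'   spikes/min.
#' @param spike_width Width of a single biphasic spike, ms.
#' @return An object of class `lfp_params`.
#' @examples
#' lfp_params()                      # untreated mutant defaults
#' lfp_params(event_rate = 0)        # electrographically silent
#' @export
lfp_params <- function(noise_sd = 10,
                       event_rate = 2,
                       event_duration_range = c(1000, 3000),
                       event_amplitude_multiple = 6,
                       spikes_per_event_range = c(5, 15),
                       interictal_spike_rate = 4,
                       spike_width = 50) {
  p <- list(noise_sd = noise_sd, event_rate = event_rate,
            event_duration_range = event_duration_range,
            event_amplitude_multiple = event_amplitude_multiple,
            spikes_per_event_range = spikes_per_event_range,
            interictal_spike_rate = interictal_spike_rate,
            spike_width = spike_width)
  stopifnot(noise_sd > 0, event_rate >= 0, interictal_spike_rate >= 0,
            length(event_duration_range) == 2L,
            length(spikes_per_event_range) == 2L,
            spike_width > 0)
  if (event_rate > 0 && event_duration_range[1] <= 500) {
    stop("qualifying events must be longer than 500 ms", call. = FALSE)
  }
  if (event_rate > 0 && event_amplitude_multiple <= 3) {
    stop("qualifying events must exceed 3x the baseline noise", call. = FALSE)
  }
  structure(p, class = "lfp_params")
}

#' 96-well plate layout for a simulated screening plate
#'
#' @param n_rows,n_cols Plate dimensions (default 8 x 12).
#' @param fish_per_compound Fish tested per compound (default 6, one row).
#' @param control_wells_per_plate Untreated internal-control wells per plate
#'   (default 6, one row).
#' @param epoch_duration Recording epoch length, s (default 600).
#' @param sample_rate Trajectory sampling rate, Hz (default 25).
#' @return An object of class `plate_design`.
#' @examples
#' plate_design()
#' @export
plate_design <- function(n_rows = 8, n_cols = 12, fish_per_compound = 6,
                         control_wells_per_plate = 6, epoch_duration = 600,
                         sample_rate = 25) {
  stopifnot(n_rows >= 1, n_cols >= 1, fish_per_compound >= 1,
            control_wells_per_plate >= 0, epoch_duration > 0, sample_rate > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 fish_per_compound = fish_per_compound,
                 control_wells_per_plate = control_wells_per_plate,
                 epoch_duration = epoch_duration, sample_rate = sample_rate),
            class = "plate_design")
}

#' Maximum number of compounds a plate design can hold
#'
#' @param design A [plate_design()].
#' @return Integer compound capacity.
#' @export
plate_capacity <- function(design) {
  total <- design$n_rows * design$n_cols
  (total - design$control_wells_per_plate) %/% design$fish_per_compound
}

#' Configuration of the three-stage seizure score
#'
#' Stage III requires a sustained bout at or above the convulsion velocity
#' threshold; Stages 0/I/II are separated by the fraction of the epoch spent
#' actively swimming. The whirlpool-like circling of Stage II is
#' operationalized as sustained high activity without supra-threshold bursts.
#'
#' @param stage3_velocity_threshold Instantaneous velocity at or above which
#'   movement counts as convulsive, mm/s (default 20).
#' @param stage3_min_bout Minimum duration a supra-threshold run must last to
#'   count as a convulsion, s.
#' @param stage0_max_active_fraction Active fraction at or below which a fish
#'   scores Stage 0 (no or very little swim activity).
#' @param stage1_max_active_fraction Active fraction at or below which a fish
#'   scores Stage I (brief swim bouts); above it, Stage II.
#' @param active_speed_threshold Instantaneous velocity above which a frame
#'   counts as active swimming, mm/s.
#' @return An object of class `stage_config`.
#' @examples
#' stage_config()
#' @export
stage_config <- function(stage3_velocity_threshold = 20,
                         stage3_min_bout = 0.5,
                         stage0_max_active_fraction = 0.05,
                         stage1_max_active_fraction = 0.25,
                         active_speed_threshold = 2) {
  stopifnot(stage3_velocity_threshold > 0, stage3_min_bout > 0,
            stage0_max_active_fraction >= 0,
            stage1_max_active_fraction > stage0_max_active_fraction,
            stage1_max_active_fraction <= 1,
            active_speed_threshold >= 0)
  structure(list(stage3_velocity_threshold = stage3_velocity_threshold,
                 stage3_min_bout = stage3_min_bout,
                 stage0_max_active_fraction = stage0_max_active_fraction,
                 stage1_max_active_fraction = stage1_max_active_fraction,
                 active_speed_threshold = active_speed_threshold),
            class = "stage_config")
}

#' Criteria for classifying a compound trial
#'
#' Thresholds for the positive-hit, toxicity and hyperexcitability rules. The
#' default suppression/excitation threshold of 44% is the 2-SD bound derived
#' from untreated-control trial-to-trial variability (SD 21.8%); the default
#' fish fraction of 0.5 implements the "at least 50% of the test fish" rule
#' (3 of 6).
#'
#' @param suppression_threshold Percent decrease in mean velocity required
#'   for a hit (positive number, default 44).
#' @param excitation_threshold Percent increase in mean velocity defining
#'   hyperexcitability (default 44).
#' @param fish_fraction Minimum fraction of fish that must qualify
#'   (default 0.5).
#' @param qualifying_stages Seizure stages counting as rescued behavior
#'   (default Stage 0 and Stage I).
#' @param viability_check_time Exposure time at which heartbeat and stimulus
#'   response are assessed, min (default 60; recorded for provenance).
#' @param per_fish_velocity If `TRUE`, the velocity criterion must hold for
#'   at least `fish_fraction` of fish individually instead of for the mean of
#'   per-fish changes (the default).
#' @return An object of class `hit_criteria`.
#' @examples
#' hit_criteria()
#' @export
hit_criteria <- function(suppression_threshold = 44,
                         excitation_threshold = 44,
                         fish_fraction = 0.5,
                         qualifying_stages = c(0, 1),
                         viability_check_time = 60,
                         per_fish_velocity = FALSE) {
  stopifnot(suppression_threshold > 0, excitation_threshold > 0,
            fish_fraction > 0, fish_fraction <= 1,
            all(qualifying_stages %in% 0:3),
            viability_check_time > 0, is.logical(per_fish_velocity))
  structure(list(suppression_threshold = suppression_threshold,
                 excitation_threshold = excitation_threshold,
                 fish_fraction = fish_fraction,
                 qualifying_stages = as.integer(qualifying_stages),
                 viability_check_time = viability_check_time,
                 per_fish_velocity = per_fish_velocity),
            class = "hit_criteria")
}

#' Configuration of the epileptiform event detector
#'
#' Events are supra-threshold excursions beyond `noise_multiple` times the
#' robust baseline noise estimate, grouped when separated by less than
#' `spike_merge_gap`; a group qualifies only if it contains at least two
#' excursions (multispike/polyspike) and spans strictly more than
#' `min_duration`.
#'
#' @param noise_multiple Threshold as a multiple of the baseline noise SD
#'   (default 3, strict).
#' @param min_duration Minimum event extent, ms (default 500, strict).
#' @param spike_merge_gap Maximum gap between excursions merged into one
#'   event, ms (default 200).
#' @param min_excursion Minimum extent of a single excursion, ms, measured
#'   first to last supra-threshold sample (default 1, i.e. at least two
#'   consecutive samples at 1 kHz); rejects one-sample noise crossings.
#' @param epoch Reference epoch length for per-epoch counts, s (default 600).
#' @param bidirectional If `TRUE` (default) both upward and downward
#'   deflections are detected.
#' @return An object of class `event_config`.
#' @examples
#' event_config()
#' @export
event_config <- function(noise_multiple = 3, min_duration = 500,
                         spike_merge_gap = 200, min_excursion = 1,
                         epoch = 600, bidirectional = TRUE) {
  stopifnot(noise_multiple > 0, min_duration > 0, spike_merge_gap >= 0,
            min_excursion >= 0, epoch > 0, is.logical(bidirectional))
  structure(list(noise_multiple = noise_multiple, min_duration = min_duration,
                 spike_merge_gap = spike_merge_gap,
                 min_excursion = min_excursion, epoch = epoch,
                 bidirectional = bidirectional),
            class = "event_config")
}
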