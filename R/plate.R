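well_names <- function(design) {
  rows <- LETTERS[seq_len(design$n_rows)]
  as.vector(t(outer(rows, seq_len(design$n_cols), paste0)))
}

#' Simulate one 96-well screening plate
#'
#' Lays out `fish_per_compound` mutant fish per compound plus one group of
#' internal-control wells, then simulates a baseline recording and a second
#' recording for every fish: compounds get the second recording under the
#' drug effect, controls get a second untreated recording after a sham media
#' change. Killing compounds set the 60-min viability flags (heartbeat,
#' stimulus response) to `FALSE` and flatten treatment movement. Per-fish
#' locomotion summaries (mean velocity, seizure stage) are computed
#' immediately; raw trajectories are retained only when
#' `keep_trajectories = TRUE`.
#'
#' @param design A [plate_design()].
#' @param effects Named list of [drug_effect()] objects, one per compound;
#'   names are compound ids.
#' @param base_params Behavior of the untreated fish, a [larva_params()]
#'   (default mutant).
#' @param concentration_um Test concentration recorded in the manifest.
#' @param stage_cfg [stage_config()] used to score treatment stages.
#' @param keep_trajectories Keep raw trajectories in the result (default
#'   `TRUE`; screen-scale simulations drop them to bound memory).
#' @param plate_id Plate identifier.
#' @param seed Optional integer seed.
#' @return An object of class `plate_dataset`: list with `plate_id`,
#'   `design`, `effects`, `summary` (per-fish data frame) and `recordings`
#'   (named list of `list(baseline, treatment)` trajectories, or `NULL`).
#' @examples
#' pl <- simulate_plate(plate_design(), list(cpdA = drug_effect("inert")),
#'                      keep_trajectories = FALSE, seed = 1)
#' head(pl$summary)
#' @export
simulate_plate <- function(design = plate_design(), effects = list(),
                           base_params = larva_params("mutant"),
                           concentration_um = 100,
                           stage_cfg = stage_config(),
                           keep_trajectories = TRUE,
                           plate_id = "P1", seed = NULL) {
  stopifnot(inherits(design, "plate_design"))
  if (length(effects) > 0 &&
      (is.null(names(effects)) || any(names(effects) == ""))) {
    stop("`effects` must be a named list keyed by compound id",
         call. = FALSE)
  }
  lapply(effects, function(e) stopifnot(inherits(e, "drug_effect")))
  n_cpd <- length(effects)
  n_wells <- n_cpd * design$fish_per_compound + design$control_wells_per_plate
  if (n_wells > design$n_rows * design$n_cols) {
    stop(sprintf("plate capacity exceeded: %d wells needed, %d available",
                 n_wells, design$n_rows * design$n_cols), call. = FALSE)
  }
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      simulate_plate(design, effects, base_params, concentration_um,
                     stage_cfg, keep_trajectories, plate_id)))
  }

  wells <- well_names(design)
  compound_of <- c(rep(names(effects), each = design$fish_per_compound),
                   rep("CONTROL", design$control_wells_per_plate))
  rows <- vector("list", length(compound_of))
  recordings <- if (keep_trajectories) list() else NULL

  for (i in seq_along(compound_of)) {
    cpd <- compound_of[i]
    fish_id <- sprintf("%s_%s", plate_id, wells[i])
    is_ctrl <- cpd == "CONTROL"
    eff <- if (is_ctrl) NULL else effects[[cpd]]
    tr_base <- simulate_trajectory(base_params, design$epoch_duration,
                                   design$sample_rate)
    p2 <- if (is_ctrl) base_params else apply_drug_effect(base_params, eff)
    tr_trt <- simulate_trajectory(p2, design$epoch_duration,
                                  design$sample_rate)
    mb <- locomotion_metrics(tr_base, stage_cfg$active_speed_threshold)
    mt <- locomotion_metrics(tr_trt, stage_cfg$active_speed_threshold)
    killed <- !is_ctrl && eff$kills
    rows[[i]] <- data.frame(
      well_id = wells[i], fish_id = fish_id, compound_id = cpd,
      concentration_um = if (is_ctrl) NA_real_ else concentration_um,
      is_control = is_ctrl,
      baseline_velocity = mb$mean_velocity,
      treatment_velocity = mt$mean_velocity,
      baseline_max_velocity = mb$max_velocity,
      treatment_max_velocity = mt$max_velocity,
      baseline_stage = score_stage(tr_base, stage_cfg),
      treatment_stage = score_stage(tr_trt, stage_cfg),
      heartbeat = !killed, stimulus_response = !killed,
      stringsAsFactors = FALSE)
    if (keep_trajectories) {
      recordings[[fish_id]] <- list(baseline = tr_base, treatment = tr_trt)
    }
  }
  structure(list(plate_id = plate_id, design = design, effects = effects,
                 summary = do.call(rbind, rows), recordings = recordings),
            class = "plate_dataset")
}

#' Extract compound trials from a simulated plate
#'
#' @param plate A `plate_dataset`.
#' @param trial Trial index recorded in the resulting objects.
#' @return Named list of [compound_trial()] objects (controls excluded).
#' @export
plate_trials <- function(plate, trial = 1L) {
  stopifnot(inherits(plate, "plate_dataset"))
  s <- plate$summary[!plate$summary$is_control, , drop = FALSE]
  out <- lapply(split(s, s$compound_id), function(d) {
    compound_trial(
      d$compound_id[1L],
      data.frame(fish_id = d$fish_id,
                 baseline_velocity = d$baseline_velocity,
                 treatment_velocity = d$treatment_velocity,
                 stage = d$treatment_stage,
                 baseline_stage = d$baseline_stage,
                 heartbeat = d$heartbeat,
                 stimulus_response = d$stimulus_response,
                 stringsAsFactors = FALSE),
      concentration_um = d$concentration_um[1L], trial = trial)
  })
  out[unique(s$compound_id)]
}

#' Extract untreated control pairs from simulated plates
#'
#' @param plates A `plate_dataset` or list of them.
#' @return Data frame with columns `baseline_velocity`, `second_velocity`,
#'   one row per control fish, pooled across plates; suitable for
#'   [control_variability()].
#' @export
control_pairs <- function(plates) {
  if (inherits(plates, "plate_dataset")) plates <- list(plates)
  do.call(rbind, lapply(plates, function(p) {
    s <- p$summary[p$summary$is_control, , drop = FALSE]
    data.frame(baseline_velocity = s$baseline_velocity,
               second_velocity = s$treatment_velocity)
  }))
}

#' Simulate a whole compound screen with ground-truth labels
#'
#' Draws an effect class for every compound from `class_frequencies`,
#' distributes compounds across as many plates as needed (each with its own
#' internal-control row), and simulates every plate. Ground-truth labels are
#' retained for confusion-matrix evaluation. Raw trajectories are not kept.
#'
#' @param n_compounds Number of compounds in the library.
#' @param class_frequencies Named numeric vector of class probabilities over
#'   `"suppressive"`, `"toxic"`, `"proconvulsant"`, `"inert"`,
#'   `"behavioral_false_positive"`; must sum to 1. The default mirrors the
#'   outcome proportions of a repurposed-library screen (about 2%
#'   suppressive, 15% toxic, 5% proconvulsant, a handful of behavioral
#'   false positives).
#' @param design A [plate_design()].
#' @param base_params Untreated behavior, a [larva_params()].
#' @param seed Optional integer seed.
#' @return An object of class `screen_dataset`: list with `compounds`
#'   (data frame `compound_id`, `effect_class`), `effects`, `plates`,
#'   `design`.
#' @examples
#' sc <- simulate_screen(30, seed = 1)
#' table(sc$compounds$effect_class)
#' @export
simulate_screen <- function(n_compounds,
                            class_frequencies = c(
                              suppressive = 0.02, toxic = 0.152,
                              proconvulsant = 0.054,
                              behavioral_false_positive = 0.003,
                              inert = 0.771),
                            design = plate_design(),
                            base_params = larva_params("mutant"),
                            seed = NULL) {
  stopifnot(n_compounds >= 1)
  classes <- c("suppressive", "toxic", "proconvulsant", "inert",
               "behavioral_false_positive")
  if (is.null(names(class_frequencies)) ||
      !all(names(class_frequencies) %in% classes)) {
    stop("`class_frequencies` must be named with effect classes",
         call. = FALSE)
  }
  if (any(class_frequencies < 0)) {
    stop("class frequencies must be non-negative", call. = FALSE)
  }
  if (abs(sum(class_frequencies) - 1) > 1e-8) {
    stop("class frequencies must sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, simulate_screen(n_compounds, class_frequencies, design,
                            base_params)))
  }

  labels <- sample(names(class_frequencies), n_compounds, replace = TRUE,
                   prob = class_frequencies)
  ids <- sprintf("CPD%04d", seq_len(n_compounds))
  effects <- lapply(labels, drug_effect)
  names(effects) <- ids

  cap <- plate_capacity(design)
  plate_of <- ceiling(seq_len(n_compounds) / cap)
  plates <- lapply(unique(plate_of), function(p) {
    simulate_plate(design, effects[plate_of == p],
                   base_params = base_params,
                   keep_trajectories = FALSE,
                   plate_id = sprintf("P%03d", p),
                   stage_cfg = stage_config())
  })
  structure(list(compounds = data.frame(compound_id = ids,
                                        effect_class = labels,
                                        stringsAsFactors = FALSE),
                 effects = effects, plates = plates, design = design),
            class = "screen_dataset")
}
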