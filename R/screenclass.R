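#' Construct a compound trial
#'
#' Per-fish summary of one compound tested at one concentration on one
#' clutch: baseline and treatment mean velocities, the treatment seizure
#' stage, and the 60-min viability flags.
#'
#' @param compound_id Compound identifier.
#' @param fish Data frame with one row per fish and columns `fish_id`,
#'   `baseline_velocity`, `treatment_velocity`, `stage` (treatment seizure
#'   stage, integer 0-3), `heartbeat`, `stimulus_response` (logical), and
#'   optionally `baseline_stage`. Baseline stages let the hyperexcitability
#'   rule count only drug-induced Stage III behavior (mutant larvae seize
#'   spontaneously, so Stage III at baseline is the unperturbed phenotype).
#' @param concentration_um Test concentration, micromolar.
#' @param trial Trial index (1 = primary screen, 2 = retest).
#' @return An object of class `compound_trial`.
#' @export
compound_trial <- function(compound_id, fish, concentration_um = 100,
                           trial = 1L) {
  need <- c("fish_id", "baseline_velocity", "treatment_velocity", "stage",
            "heartbeat", "stimulus_response")
  if (!is.data.frame(fish) || !all(need %in% names(fish))) {
    stop("`fish` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(fish) < 1L) stop("trial needs at least one fish", call. = FALSE)
  if (is.null(fish$baseline_stage)) fish$baseline_stage <- NA_integer_
  stopifnot(all(fish$stage %in% 0:3),
            all(is.na(fish$baseline_stage) | fish$baseline_stage %in% 0:3),
            is.logical(fish$heartbeat), is.logical(fish$stimulus_response))
  structure(list(compound_id = compound_id, fish = fish,
                 concentration_um = concentration_um,
                 trial = as.integer(trial)),
            class = "compound_trial")
}

#' Trial-to-trial variability of untreated controls
#'
#' Pools per-fish percent changes in mean velocity between two consecutive
#' untreated recordings and returns their sample standard deviation (n - 1
#' denominator). This control variability sets the screen's detection
#' threshold via [derive_threshold()]. Fish with non-positive baseline
#' velocity are excluded with a warning.
#'
#' @param control_pairs Data frame with columns `baseline_velocity` and
#'   `second_velocity` (one row per control fish, poolable across plates),
#'   or a list of such data frames.
#' @return An object of class `control_stats`: list with `n`,
#'   `mean_percent_change`, `sd_percent_change`, `percent_changes`.
#' @examples
#' cp <- data.frame(baseline_velocity = c(10, 10),
#'                  second_velocity = c(9, 11))
#' control_variability(cp)$sd_percent_change   # 14.14
#' @export
control_variability <- function(control_pairs) {
  if (is.list(control_pairs) && !is.data.frame(control_pairs)) {
    control_pairs <- do.call(rbind, control_pairs)
  }
  need <- c("baseline_velocity", "second_velocity")
  if (!is.data.frame(control_pairs) || !all(need %in% names(control_pairs))) {
    stop("`control_pairs` must have columns baseline_velocity, ",
         "second_velocity", call. = FALSE)
  }
  ok <- control_pairs$baseline_velocity > 0
  if (any(!ok)) {
    warning(sum(!ok), " control fish with zero baseline velocity excluded")
  }
  cp <- control_pairs[ok, , drop = FALSE]
  if (nrow(cp) < 2L) {
    stop("need at least two valid control pairs", call. = FALSE)
  }
  pc <- 100 * (cp$second_velocity - cp$baseline_velocity) /
    cp$baseline_velocity
  structure(list(n = nrow(cp), mean_percent_change = mean(pc),
                 sd_percent_change = stats::sd(pc), percent_changes = pc),
            class = "control_stats")
}

#' Detection threshold from control variability
#'
#' The hit threshold is `k_sd` standard deviations of the untreated-control
#' percent-change distribution, rounded up to the next integer percent: with
#' the observed control SD of 21.8 and the default 2 SDs this reproduces the
#' 44% threshold used for both suppression and hyperexcitability.
#'
#' @param stats A `control_stats` object from [control_variability()], or a
#'   single numeric SD in percent.
#' @param k_sd Number of standard deviations (default 2).
#' @return Integer threshold in percent.
#' @examples
#' derive_threshold(21.8)   # 44
#' @export
derive_threshold <- function(stats, k_sd = 2) {
  sd <- if (inherits(stats, "control_stats")) stats$sd_percent_change
        else stats
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0, k_sd > 0)
  as.integer(ceiling(k_sd * sd))
}

#' Classify one compound trial
#'
#' Applies the screen's decision rules with precedence
#' toxic > hyperexcitable > hit > inactive:
#' \itemize{
#'   \item \strong{toxic}: at least `fish_fraction` of the fish show neither
#'     heartbeat nor movement in response to stimulation at the 60-min
#'     viability check.
#'   \item \strong{hyperexcitable}: mean per-fish velocity change of at
#'     least `+excitation_threshold`, and/or drug-induced Stage III seizure
#'     behavior in at least `fish_fraction` of surviving fish. Because
#'     mutant larvae convulse spontaneously, a fish counts toward the Stage
#'     III clause only if it was below Stage III at baseline (fish with
#'     unknown baseline stage always count).
#'   \item \strong{hit}: mean per-fish velocity change of
#'     `-suppression_threshold` or lower, and Stage 0 or I behavior in at
#'     least `fish_fraction` of surviving fish.
#'   \item \strong{inactive}: everything else.
#' }
#' Dead fish are excluded from velocity means and stage counts; fish with
#' zero baseline velocity are excluded with a warning.
#'
#' @param trial A [compound_trial()].
#' @param criteria A [hit_criteria()].
#' @return An object of class `classification`: list with `compound_id`,
#'   `concentration_um`, `trial`, `label`, `per_fish_changes`, `n_fish`,
#'   `n_alive`, `n_qualifying_stage`, `n_stage3`, `mean_percent_change`.
#' @examples
#' fish <- data.frame(fish_id = 1:6, baseline_velocity = 10,
#'                    treatment_velocity = 4, stage = 0L,
#'                    heartbeat = TRUE, stimulus_response = TRUE)
#' classify_compound(compound_trial("cpd", fish))$label   # "hit"
#' @export
classify_compound <- function(trial, criteria = hit_criteria()) {
  stopifnot(inherits(trial, "compound_trial"),
            inherits(criteria, "hit_criteria"))
  fish <- trial$fish
  n_fish <- nrow(fish)
  dead <- !fish$heartbeat & !fish$stimulus_response
  n_alive <- sum(!dead)

  alive <- fish[!dead, , drop = FALSE]
  valid <- alive$baseline_velocity > 0
  if (any(!valid)) {
    warning(sum(!valid), " fish with zero baseline velocity excluded from ",
            "compound ", trial$compound_id)
  }
  av <- alive[valid, , drop = FALSE]
  if (nrow(av) == 0L && sum(dead) / n_fish < criteria$fish_fraction) {
    stop("no valid fish in trial for compound ", trial$compound_id,
         call. = FALSE)
  }
  pc <- if (nrow(av) > 0L) {
    100 * (av$treatment_velocity - av$baseline_velocity) /
      av$baseline_velocity
  } else numeric(0)
  mean_pc <- if (length(pc)) mean(pc) else NA_real_
  n_qual <- sum(av$stage %in% criteria$qualifying_stages)
  n_stage3 <- sum(av$stage == 3L &
                    (is.na(av$baseline_stage) | av$baseline_stage < 3L))
  n_scored <- nrow(av)

  frac_ok <- function(k, n) n > 0L && k / n >= criteria$fish_fraction
  vel_suppressed <- if (criteria$per_fish_velocity) {
    frac_ok(sum(pc <= -criteria$suppression_threshold), length(pc))
  } else {
    length(pc) > 0L && mean_pc <= -criteria$suppression_threshold
  }
  vel_excited <- if (criteria$per_fish_velocity) {
    frac_ok(sum(pc >= criteria$excitation_threshold), length(pc))
  } else {
    length(pc) > 0L && mean_pc >= criteria$excitation_threshold
  }

  label <- if (sum(dead) / n_fish >= criteria$fish_fraction) {
    "toxic"
  } else if (vel_excited || frac_ok(n_stage3, n_scored)) {
    "hyperexcitable"
  } else if (vel_suppressed && frac_ok(n_qual, n_scored)) {
    "hit"
  } else {
    "inactive"
  }
  structure(list(compound_id = trial$compound_id,
                 concentration_um = trial$concentration_um,
                 trial = trial$trial, label = label,
                 per_fish_changes = pc, n_fish = n_fish, n_alive = n_alive,
                 n_qualifying_stage = n_qual, n_stage3 = n_stage3,
                 mean_percent_change = mean_pc),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("%s (trial %d): %s  [mean change %+.1f%%, %d/%d alive, %d low-stage]\n",
              x$compound_id, x$trial, toupper(x$label),
              x$mean_percent_change, x$n_alive, x$n_fish,
              x$n_qualifying_stage))
  invisible(x)
}

#' Confirm a hit across two independent trials
#'
#' A compound is a confirmed hit only if it is classified a hit in both
#' independent trials (separate clutches) and is not classified toxic in
#' either.
#'
#' @param trial1,trial2 `classification` objects for the same compound.
#' @return `TRUE` or `FALSE`.
#' @examples
#' \dontrun{confirm_hit(cls1, cls2)}
#' @export
confirm_hit <- function(trial1, trial2) {
  stopifnot(inherits(trial1, "classification"),
            inherits(trial2, "classification"))
  if (!identical(trial1$compound_id, trial2$compound_id)) {
    stop("classifications are for different compounds", call. = FALSE)
  }
  trial1$label == "hit" && trial2$label == "hit"
}
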