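#' Configuration for an end-to-end simulated screen
#'
#' Collects every tunable of the two-stage pipeline with its screen default:
#' 44% velocity threshold (re-derived from each screen's own controls unless
#' `derive_threshold_from_controls = FALSE`), 50% fish fraction, 20 mm/s
#' Stage III velocity, 3x noise and 500 ms event gates, 600 s epochs.
#'
#' @param n_compounds Library size (default 1012).
#' @param class_frequencies Passed to [simulate_screen()].
#' @param design A [plate_design()].
#' @param base_params Untreated mutant behavior, a [larva_params()].
#' @param criteria A [hit_criteria()]; its suppression/excitation thresholds
#'   are replaced by the control-derived value when
#'   `derive_threshold_from_controls` is `TRUE`.
#' @param stage_cfg A [stage_config()].
#' @param event_cfg An [event_config()].
#' @param lfp_baseline [lfp_params()] describing untreated mutant
#'   electrographic activity.
#' @param ephys_fish Fish per compound in the electrophysiology stage.
#' @param ephys_duration,ephys_rate LFP recording length (s) and sampling
#'   rate (Hz).
#' @param min_reduction Reduction fraction required for a suppression call.
#' @param derive_threshold_from_controls Re-derive the velocity threshold
#'   from this screen's pooled control variability (2 SDs, rounded up).
#' @param ephys_on_all Run the electrophysiology stage on every compound
#'   instead of only confirmed hits (study mode; default `FALSE`).
#' @return An object of class `screen_run_config`.
#' @export
screen_config <- function(n_compounds = 1012,
                          class_frequencies = NULL,
                          design = plate_design(),
                          base_params = larva_params("mutant"),
                          criteria = hit_criteria(),
                          stage_cfg = stage_config(),
                          event_cfg = event_config(),
                          lfp_baseline = lfp_params(),
                          ephys_fish = 6,
                          ephys_duration = 600,
                          ephys_rate = 1000,
                          min_reduction = 0.9,
                          derive_threshold_from_controls = TRUE,
                          ephys_on_all = FALSE) {
  cfg <- list(n_compounds = n_compounds,
              class_frequencies = class_frequencies,
              design = design, base_params = base_params,
              criteria = criteria, stage_cfg = stage_cfg,
              event_cfg = event_cfg, lfp_baseline = lfp_baseline,
              ephys_fish = ephys_fish, ephys_duration = ephys_duration,
              ephys_rate = ephys_rate, min_reduction = min_reduction,
              derive_threshold_from_controls = derive_threshold_from_controls,
              ephys_on_all = ephys_on_all)
  stopifnot(n_compounds >= 1, ephys_fish >= 1, ephys_duration > 0,
            ephys_rate >= 200, min_reduction >= 0, min_reduction <= 1)
  structure(cfg, class = "screen_run_config")
}

#' Summarize the two-stage screening funnel
#'
#' Counts each stage of the funnel: library tested, first-trial labels,
#' hits confirmed in two independent trials, and electrographically
#' suppressed confirmed hits. The hit rate is reported in percent truncated
#' (not rounded) to two decimals, so 20 hits of 1012 compounds is 1.97.
#'
#' @param trial1 First-trial labels: a character vector (one label per
#'   compound, optionally named), a data frame with columns `compound_id`
#'   and `label`, or a list of `classification` objects.
#' @param trial2 Optional second-trial labels for retested compounds, same
#'   forms, named by or containing compound ids.
#' @param ephys_calls Optional named logical vector (or named list of
#'   `suppression_call`) of electrographic suppression for confirmed hits.
#' @return An object of class `screen_summary`: list with `n_tested`,
#'   `n_hits_stage1`, `hit_rate`, `n_toxic`, `n_hyperexcitable`,
#'   `n_inactive`, `n_confirmed`, `n_ephys_suppressed`.
#' @examples
#' labels <- c(rep("hit", 20), rep("inactive", 992))
#' funnel_summary(labels)$hit_rate   # 1.97
#' @export
funnel_summary <- function(trial1, trial2 = NULL, ephys_calls = NULL) {
  lab1 <- as_label_vector(trial1)
  if (length(lab1) == 0L) {
    stop("no compounds in screen", call. = FALSE)
  }
  valid <- c("hit", "toxic", "hyperexcitable", "inactive")
  if (any(is.na(lab1)) || !all(lab1 %in% valid)) {
    stop("incomplete screen: every compound needs a stage-1 label",
         call. = FALSE)
  }
  n <- length(lab1)
  n_hits <- sum(lab1 == "hit")
  hit_rate <- trunc(100 * n_hits / n * 100) / 100

  n_confirmed <- NA_integer_
  if (!is.null(trial2)) {
    lab2 <- as_label_vector(trial2)
    hits1 <- names(lab1)[lab1 == "hit"]
    if (is.null(hits1)) {
      stop("confirmation requires named labels", call. = FALSE)
    }
    common <- intersect(hits1, names(lab2))
    n_confirmed <- sum(lab2[common] == "hit")
  }
  n_suppressed <- NA_integer_
  if (!is.null(ephys_calls)) {
    if (is.list(ephys_calls)) {
      ephys_calls <- vapply(ephys_calls, function(x) {
        if (inherits(x, "suppression_call")) x$suppressed else isTRUE(x)
      }, logical(1))
    }
    n_suppressed <- sum(ephys_calls)
    if (!is.na(n_confirmed) && n_suppressed > n_confirmed) {
      stop("more suppression calls than confirmed hits", call. = FALSE)
    }
  }
  structure(list(n_tested = n, n_hits_stage1 = n_hits, hit_rate = hit_rate,
                 n_toxic = sum(lab1 == "toxic"),
                 n_hyperexcitable = sum(lab1 == "hyperexcitable"),
                 n_inactive = sum(lab1 == "inactive"),
                 n_confirmed = n_confirmed,
                 n_ephys_suppressed = n_suppressed),
            class = "screen_summary")
}

as_label_vector <- function(x) {
  if (inherits(x, "classification")) x <- list(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("compound_id", "label") %in% names(x)))
    return(stats::setNames(as.character(x$label), x$compound_id))
  }
  if (is.list(x)) {
    return(stats::setNames(
      vapply(x, function(cl) cl$label, character(1)),
      vapply(x, function(cl) as.character(cl$compound_id), character(1))))
  }
  if (is.character(x)) return(x)
  stop("cannot interpret labels", call. = FALSE)
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Screen of %d compounds: %d hits (%.2f%%), %d toxic, %d hyperexcitable, %d inactive\n",
              x$n_tested, x$n_hits_stage1, x$hit_rate, x$n_toxic,
              x$n_hyperexcitable, x$n_inactive))
  if (!is.na(x$n_confirmed)) {
    cat(sprintf("  confirmed in two trials: %d", x$n_confirmed))
    if (!is.na(x$n_ephys_suppressed)) {
      cat(sprintf("; electrographically suppressed: %d",
                  x$n_ephys_suppressed))
    }
    cat("\n")
  }
  invisible(x)
}

#' Long-format per-fish table for heat-map display
#'
#' One row per (compound, trial, fish) with the per-fish percent velocity
#' change, mirroring the per-fish heat map used to display screen results.
#'
#' @param trials List of [compound_trial()] objects (may span trials 1
#'   and 2).
#' @return Data frame with columns `compound_id`, `concentration_um`,
#'   `trial`, `fish`, `fish_id`, `pct_change`. Empty input yields an empty
#'   table with the same columns.
#' @export
heatmap_table <- function(trials) {
  cols <- data.frame(compound_id = character(0),
                     concentration_um = numeric(0), trial = integer(0),
                     fish = integer(0), fish_id = character(0),
                     pct_change = numeric(0), stringsAsFactors = FALSE)
  if (length(trials) == 0L) return(cols)
  if (inherits(trials, "compound_trial")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    stopifnot(inherits(tr, "compound_trial"))
    f <- tr$fish
    pc <- ifelse(f$baseline_velocity > 0,
                 100 * (f$treatment_velocity - f$baseline_velocity) /
                   f$baseline_velocity, NA_real_)
    data.frame(compound_id = tr$compound_id,
               concentration_um = tr$concentration_um,
               trial = tr$trial, fish = seq_len(nrow(f)),
               fish_id = as.character(f$fish_id), pct_change = pc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full two-stage screen on simulated data
#'
#' Orchestrates the funnel: simulate the library, derive the velocity
#' threshold from the screen's own pooled controls (2 SDs of the
#' percent-change SD, rounded up), classify every compound (trial 1),
#' retest trial-1 hits on an independent clutch (trial 2), and run the
#' electrophysiology stage on confirmed non-toxic hits, calling
#' electrographic suppression against an untreated mutant reference.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param out_dir Optional directory to write artifacts to: `summary.json`,
#'   `compounds.tsv`, `heatmap.csv`, `ephys.tsv`, `run_log.json`.
#' @return An object of class `screen_run`: list with `summary`
#'   (a `screen_summary`), `compounds` (per-compound data frame with ground
#'   truth, per-trial labels, confirmation and suppression), `threshold`
#'   (percent), `control_stats`, `ephys` (per-compound suppression data
#'   frame), and `seed`.
#' @examples
#' \donttest{
#' res <- run_screen(screen_config(n_compounds = 15), seed = 1)
#' res$summary
#' }
#' @export
run_screen <- function(config = screen_config(), seed = 1L,
                       out_dir = NULL) {
  stopifnot(inherits(config, "screen_run_config"))
  withr::with_seed(seed, run_screen_impl(config, seed, out_dir))
}

run_screen_impl <- function(config, seed, out_dir) {
  freq_args <- list(n_compounds = config$n_compounds,
                    design = config$design,
                    base_params = config$base_params)
  if (!is.null(config$class_frequencies)) {
    freq_args$class_frequencies <- config$class_frequencies
  }
  screen <- do.call(simulate_screen, freq_args)

  cstats <- control_variability(control_pairs(screen$plates))
  criteria <- config$criteria
  if (config$derive_threshold_from_controls) {
    thr <- derive_threshold(cstats)
    criteria$suppression_threshold <- thr
    criteria$excitation_threshold <- thr
  } else {
    thr <- criteria$suppression_threshold
  }

  trials1 <- unlist(lapply(screen$plates, plate_trials, trial = 1L),
                    recursive = FALSE)
  cls1 <- lapply(trials1, classify_compound, criteria = criteria)
  lab1 <- as_label_vector(cls1)

  # retest trial-1 hits on an independent clutch
  hit_ids <- names(lab1)[lab1 == "hit"]
  cls2 <- list()
  trials2 <- list()
  if (length(hit_ids) > 0L) {
    cap <- plate_capacity(config$design)
    grp <- ceiling(seq_along(hit_ids) / cap)
    for (g in unique(grp)) {
      ids <- hit_ids[grp == g]
      pl <- simulate_plate(config$design, screen$effects[ids],
                           base_params = config$base_params,
                           stage_cfg = config$stage_cfg,
                           keep_trajectories = FALSE,
                           plate_id = sprintf("R%03d", g))
      trials2 <- c(trials2, plate_trials(pl, trial = 2L))
    }
    cls2 <- lapply(trials2, classify_compound, criteria = criteria)
  }
  lab2 <- if (length(cls2)) as_label_vector(cls2) else character(0)
  confirmed <- names(lab2)[lab2 == "hit"]

  # electrophysiology stage
  ephys_ids <- if (config$ephys_on_all) screen$compounds$compound_id
               else confirmed
  ephys <- data.frame(compound_id = character(0), treated_count = numeric(0),
                      reference_count = numeric(0),
                      reduction_fraction = numeric(0),
                      suppressed = logical(0), stringsAsFactors = FALSE)
  calls <- NULL
  if (length(ephys_ids) > 0L) {
    ref_counts <- vapply(seq_len(config$ephys_fish), function(i) {
      sim <- simulate_lfp(config$lfp_baseline, config$ephys_duration,
                          config$ephys_rate)
      epoch_event_count(detect_events(sim$trace, config$event_cfg),
                        recorded = config$ephys_duration,
                        epoch = config$event_cfg$epoch)
    }, numeric(1))
    ref <- mean(ref_counts)
    rows <- lapply(ephys_ids, function(id) {
      eff <- screen$effects[[id]]
      p <- config$lfp_baseline
      p$event_rate <- p$event_rate * eff$lfp_event_rate_scale
      counts <- vapply(seq_len(config$ephys_fish), function(i) {
        sim <- simulate_lfp(p, config$ephys_duration, config$ephys_rate)
        epoch_event_count(detect_events(sim$trace, config$event_cfg),
                          recorded = config$ephys_duration,
                          epoch = config$event_cfg$epoch)
      }, numeric(1))
      call <- suppression_call(mean(counts), ref, config$min_reduction)
      data.frame(compound_id = id, treated_count = call$treated_count,
                 reference_count = call$reference_count,
                 reduction_fraction = call$reduction_fraction,
                 suppressed = call$suppressed, stringsAsFactors = FALSE)
    })
    ephys <- do.call(rbind, rows)
    calls <- stats::setNames(ephys$suppressed, ephys$compound_id)
  }

  summary <- funnel_summary(lab1, if (length(lab2)) lab2 else NULL,
                            if (length(confirmed)) calls[confirmed]
                            else NULL)

  compounds <- screen$compounds
  compounds$label_trial1 <- unname(lab1[compounds$compound_id])
  compounds$label_trial2 <- unname(lab2[compounds$compound_id])
  compounds$confirmed <- compounds$compound_id %in% confirmed
  compounds$suppressed <- unname(calls[compounds$compound_id])
  compounds$mean_pct_change <- vapply(cls1, function(x)
    x$mean_percent_change, numeric(1))[compounds$compound_id]

  res <- structure(list(summary = summary, compounds = compounds,
                        threshold = thr, control_stats = cstats,
                        ephys = ephys,
                        trials1 = trials1, trials2 = trials2,
                        seed = seed, config = config),
                   class = "screen_run")
  if (!is.null(out_dir)) write_screen_artifacts(res, out_dir)
  res
}

#' @export
print.screen_run <- function(x, ...) {
  cat(sprintf("Two-stage screen (seed %d, threshold %d%%)\n", x$seed,
              x$threshold))
  print(x$summary)
  invisible(x)
}
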