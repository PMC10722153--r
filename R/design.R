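#' Experimental design constants
#'
#' Builds the layout of the grasping experiment: four action conditions
#' (DG: direct grasp, AG: air grasp, NG: non-grasp, UG: uninformed grasp)
#' crossed with two object orientations (+45 / -45 degrees), trials split
#' into instruction, action and judgment phases separated by waiting
#' periods, acquired in runs of 16 trials at a TR of 2 s.
#'
#' Each trial lasts 24 s (instruction 1 s, wait 5 s, action 4 s, wait 8 s,
#' judgment 2 s, inter-trial interval 4 s). A run of 16 trials therefore
#' spans 384 s; with 198 acquired volumes (396 s) the remaining 12 s are
#' baseline: `lead_in_volumes` volumes prepended to the run and the rest
#' appended after the final trial, so the lagged measurement windows of
#' the last trial's judgment phase stay inside the run.
#'
#' @param overrides named list replacing any default field.
#' @return An object of class `grasp_design` (a named list).
#' @examples
#' d <- build_design()
#' total_trials(d)  # 160
#' @export
build_design <- function(overrides = list()) {
  design <- list(
    tr_seconds = 2,
    volumes_per_run = 198L,
    n_runs = 10L,
    trials_per_run = 16L,
    n_participants = 10L,
    repetitions_per_setting = 20L,
    conditions = c("DG", "AG", "NG", "UG"),
    orientations = c("+45", "-45"),
    phase_durations_seconds = c(
      instruction = 1, wait1 = 5, action = 4, wait2 = 8,
      judgment = 2, iti = 4
    ),
    lead_in_volumes = 3L
  )
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(design))
    if (length(unknown)) {
      stop("unknown design field(s): ", paste(unknown, collapse = ", "))
    }
    design[names(overrides)] <- overrides
  }
  class(design) <- "grasp_design"
  validate_design(design)
  design
}

#' Validate a design against its structural invariants
#'
#' @param design a `grasp_design`.
#' @return the design, invisibly; errors name the violated invariant.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "grasp_design"))
  n_settings <- length(design$conditions) * length(design$orientations)
  total <- design$n_runs * design$trials_per_run
  expected <- n_settings * design$repetitions_per_setting
  if (total != expected) {
    stop(
      "invariant violated: n_runs x trials_per_run (", total,
      ") != settings x repetitions_per_setting (", expected, ")"
    )
  }
  run_seconds <- design$trials_per_run * trial_duration_seconds(design) +
    design$lead_in_volumes * design$tr_seconds
  if (run_seconds > design$volumes_per_run * design$tr_seconds) {
    stop(
      "invariant violated: trials + lead-in (", run_seconds,
      " s) exceed run length (",
      design$volumes_per_run * design$tr_seconds, " s)"
    )
  }
  if (anyDuplicated(design$conditions) || anyDuplicated(design$orientations)) {
    stop("invariant violated: conditions and orientations must be unique")
  }
  invisible(design)
}

#' Total trial count of a design
#' @param design a `grasp_design`.
#' @export
total_trials <- function(design) {
  design$n_runs * design$trials_per_run
}

#' Trial duration in seconds (sum of all phase durations)
#' @param design a `grasp_design`.
#' @export
trial_duration_seconds <- function(design) {
  sum(design$phase_durations_seconds)
}

#' Onset of each phase relative to trial onset, in seconds
#' @param design a `grasp_design`.
#' @return named numeric vector of within-trial phase onsets.
#' @export
phase_offsets_seconds <- function(design) {
  d <- design$phase_durations_seconds
  stats::setNames(cumsum(c(0, d[-length(d)])), names(d))
}

#' Build a randomized trial table for one participant
#'
#' The per-participant multiset of the eight settings (condition x
#' orientation), each repeated `repetitions_per_setting` times, is dealt
#' into runs and shuffled within each run. When the repetition count is
#' divisible by the number of runs (the default: 20 repetitions over 10
#' runs), every setting occurs equally often in every run; this
#' run-balanced randomization keeps leave-one-run-out folds
#' class-balanced, without which cross-validated accuracy on
#' information-free data is biased below chance. Otherwise the multiset
#' is shuffled without the per-run constraint. Trial onsets are the
#' lead-in time plus cumulative trial durations.
#'
#' @param design a `grasp_design`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param participant participant id recorded in the table.
#' @return tibble with columns `participant`, `run`, `trial`, `condition`,
#'   `orientation`, `onset` (seconds from run start).
#' @export
build_trial_table <- function(design, seed = NULL, participant = 1L) {
  validate_design(design)
  if (!is.null(seed)) set.seed(seed)
  settings <- expand.grid(
    orientation = design$orientations,
    condition = design$conditions,
    stringsAsFactors = FALSE
  )
  reps <- design$repetitions_per_setting
  n_runs <- design$n_runs
  if (reps %% n_runs == 0) {
    per_run <- reps %/% n_runs
    pool <- settings[rep(seq_len(nrow(settings)), each = reps), ]
    pool$run <- rep(rep(seq_len(n_runs), each = per_run), nrow(settings))
    pool <- pool[order(pool$run), ]
    within_run <- unlist(lapply(
      split(seq_len(nrow(pool)), pool$run),
      function(idx) idx[sample.int(length(idx))]
    ), use.names = FALSE)
    pool <- pool[within_run, ]
  } else {
    pool <- settings[rep(seq_len(nrow(settings)), each = reps), ]
    pool <- pool[sample.int(nrow(pool)), ]
    pool$run <- rep(seq_len(n_runs), each = design$trials_per_run)
  }
  lead_in <- design$lead_in_volumes * design$tr_seconds
  trial <- rep(seq_len(design$trials_per_run), n_runs)
  tibble::tibble(
    participant = as.integer(participant),
    run = rep(seq_len(n_runs), each = design$trials_per_run),
    trial = as.integer(trial),
    condition = pool$condition,
    orientation = pool$orientation,
    onset = lead_in + (trial - 1) * trial_duration_seconds(design)
  )
}

#' Convert a phase onset to a 0-based volume index
#'
#' Volume `v` covers the half-open interval `[v * TR, (v + 1) * TR)`;
#' the index of the volume containing a phase onset is
#' `floor(onset / TR)`.
#'
#' @param trial_onset_seconds trial onset(s) from run start (vectorized).
#' @param phase one of `instruction`, `wait1`, `action`, `wait2`,
#'   `judgment`, `iti`.
#' @param design a `grasp_design`.
#' @return integer vector of 0-based volume indices.
#' @export
phase_volume_index <- function(trial_onset_seconds, phase, design) {
  offsets <- phase_offsets_seconds(design)
  if (!phase %in% names(offsets)) {
    stop("unknown phase: ", phase)
  }
  onset <- trial_onset_seconds + offsets[[phase]]
  vol <- floor(onset / design$tr_seconds)
  if (any(vol < 0 | vol >= design$volumes_per_run)) {
    stop(
      "phase onset outside run: volume index ",
      paste(vol[vol < 0 | vol >= design$volumes_per_run], collapse = ", "),
      " not in [0, ", design$volumes_per_run - 1, "]"
    )
  }
  as.integer(vol)
}

#' @export
print.grasp_design <- function(x, ...) {
  cat("Experiment design:\n")
  cat(
    " ", x$n_participants, "participants,", x$n_runs, "runs x",
    x$trials_per_run, "trials,", total_trials(x), "trials total\n"
  )
  cat(
    " ", length(x$conditions) * length(x$orientations),
    "settings:", paste(x$conditions, collapse = "/"), "x",
    paste(x$orientations, collapse = "/"), "\n"
  )
  cat(
    "  TR", x$tr_seconds, "s,", x$volumes_per_run, "volumes/run,",
    x$lead_in_volumes, "lead-in volumes\n"
  )
  invisible(x)
}
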