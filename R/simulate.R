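#' Simulate one ROI x run BOLD matrix
#'
#' Builds the voxels x volumes signal for one scanner run of one ROI:
#'
#' `signal = baseline * (1 + (universal + orientation) / 100) + drift + noise`
#'
#' where `universal` is the condition-independent evoked response (every
#' task phase of every trial convolved with the unit-peak HRF kernel of
#' its duration, scaled by the universal amplitude) and `orientation` is
#' the cell-specific term `sign(orientation) * amplitude * pattern`,
#' convolved the same way. The action-phase pattern is multiplied by the
#' (ROI, condition) cross-phase sign. Noise is AR(1) Gaussian per voxel
#' with the stated marginal SD; drift is a per-voxel linear + quadratic
#' polynomial with Gaussian coefficients.
#'
#' @param design a `grasp_design`.
#' @param trials_run trial-table rows of a single run.
#' @param truth a `ground_truth` containing `roi`.
#' @param roi ROI name.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param universal optional precomputed universal-response time course
#'   (percent of baseline, one value per volume); it depends only on the
#'   trial onsets, so callers simulating several ROIs of the same run
#'   can share it.
#' @return object of class `roi_timeseries`: list with `participant`,
#'   `run`, `roi`, `matrix` (voxels x volumes), `voxel_ids`.
#' @export
simulate_roi_run <- function(design, trials_run, truth, roi, seed = NULL,
                             universal = NULL) {
  if (!roi %in% truth$roi_names) {
    stop("ROI '", roi, "' absent from ground truth")
  }
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(unique(trials_run$run)) == 1)

  nv <- truth$n_voxels_per_roi[[roi]]
  n_vol <- design$volumes_per_run
  base <- truth$baseline_level
  vol_times <- (seq_len(n_vol) - 1) * design$tr_seconds
  offsets <- phase_offsets_seconds(design)
  task_phases <- c("instruction", "action", "judgment")
  kernels <- lapply(
    stats::setNames(task_phases, task_phases),
    function(ph) .cached_kernel(design$phase_durations_seconds[[ph]])
  )

  # condition-independent evoked response, percent of baseline
  if (is.null(universal)) {
    universal <- .universal_course(design, trials_run, truth, kernels)
  }

  # orientation term: per informative (condition, phase) cell a signed
  # scalar time course, multiplied into the cell's voxel pattern
  pattern_part <- matrix(0, nrow = nv, ncol = n_vol)
  cells_roi <- truth$cells[truth$cells$roi == roi, ]
  if (nrow(cells_roi)) {
    ori_sign <- ifelse(trials_run$orientation == design$orientations[1], 1, -1)
    for (i in seq_len(nrow(cells_roi))) {
      cond <- cells_roi$condition[i]
      ph <- cells_roi$phase[i]
      amp <- cells_roi$amplitude[i]
      if (amp == 0) next
      idx <- which(trials_run$condition == cond)
      if (!length(idx)) next
      s <- numeric(n_vol)
      for (j in idx) {
        s <- s + ori_sign[j] *
          kernel_value(kernels[[ph]], vol_times -
                         (trials_run$onset[j] + offsets[[ph]]))
      }
      pat <- truth$pattern_bank[[cells_roi$pattern_id[i]]]
      if (ph == "action") {
        pat <- pat * truth$cross_phase_sign[[paste(roi, cond, sep = ".")]]
      }
      pattern_part <- pattern_part + amp * outer(pat, s)
    }
  }

  m <- base * (1 + (rep(1, nv) %o% universal + pattern_part) / 100)

  if (truth$drift_amplitude > 0) {
    x <- seq(-1, 1, length.out = n_vol)
    c1 <- stats::rnorm(nv, sd = truth$drift_amplitude)
    c2 <- stats::rnorm(nv, sd = truth$drift_amplitude)
    m <- m + outer(c1, x) + outer(c2, x^2)
  }
  if (truth$noise_sd > 0) {
    m <- m + .ar1_noise(nv, n_vol, truth$noise_sd, truth$ar1_coefficient)
  }

  structure(
    list(
      participant = trials_run$participant[1],
      run = trials_run$run[1],
      roi = roi,
      matrix = m,
      voxel_ids = seq_len(nv)
    ),
    class = "roi_timeseries"
  )
}

# universal (condition-independent) evoked response time course,
# percent of baseline, one value per volume
.universal_course <- function(design, trials_run, truth, kernels = NULL) {
  task_phases <- c("instruction", "action", "judgment")
  if (is.null(kernels)) {
    kernels <- lapply(
      stats::setNames(task_phases, task_phases),
      function(ph) .cached_kernel(design$phase_durations_seconds[[ph]])
    )
  }
  vol_times <- (seq_len(design$volumes_per_run) - 1) * design$tr_seconds
  offsets <- phase_offsets_seconds(design)
  universal <- numeric(design$volumes_per_run)
  for (ph in task_phases) {
    for (onset in trials_run$onset + offsets[[ph]]) {
      universal <- universal +
        truth$universal_response_amplitude *
          kernel_value(kernels[[ph]], vol_times - onset)
    }
  }
  universal
}

# AR(1) noise, voxels x volumes, stationary with marginal sd `sd`
.ar1_noise <- function(n_voxels, n_volumes, sd, phi) {
  if (abs(phi) >= 1) stop("AR(1) coefficient must satisfy |phi| < 1")
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(stats::rnorm(n_voxels * n_volumes, sd = innov_sd),
              nrow = n_voxels, ncol = n_volumes)
  e[, 1] <- stats::rnorm(n_voxels, sd = sd)  # stationary start
  for (t in 2:n_volumes) {
    e[, t] <- e[, t] + phi * e[, t - 1]
  }
  e
}

#' Simulate motion traces for one or more participants
#'
#' Per run: a bounded random walk in three translation axes (mm) and
#' three rotation axes (degrees) relative to the first volume, which is
#' zero by construction. Clean runs are rescaled to stay strictly below
#' both exclusion thresholds; contaminated runs receive a translation
#' step that exceeds 2 mm.
#'
#' @param design a `grasp_design`.
#' @param seed integer seed, or `NULL`.
#' @param contaminated_runs run indices given excessive motion (applied
#'   to every participant).
#' @param participants participant ids to simulate.
#' @return tibble: `participant`, `run`, `volume` (0-based), `tx`, `ty`,
#'   `tz` (mm), `rx`, `ry`, `rz` (degrees).
#' @export
simulate_motion <- function(design, seed = NULL,
                            contaminated_runs = integer(0),
                            participants = seq_len(design$n_participants)) {
  if (!all(contaminated_runs %in% seq_len(design$n_runs))) {
    stop("contaminated_runs outside 1..n_runs")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(participants, function(p) {
    dplyr::bind_rows(lapply(seq_len(design$n_runs), function(r) {
      .simulate_motion_run(design, p, r, r %in% contaminated_runs)
    }))
  })
  dplyr::bind_rows(out)
}

.simulate_motion_run <- function(design, participant, run, contaminated) {
  n_vol <- design$volumes_per_run
  walk <- function(cap) {
    w <- cumsum(c(0, stats::rnorm(n_vol - 1, sd = 0.03)))
    peak <- max(abs(w))
    if (peak > cap) w <- w * cap / peak
    w
  }
  tr <- replicate(3, walk(1.2))
  ro <- replicate(3, walk(0.8))
  if (contaminated) {
    jump_at <- sample(seq(n_vol %/% 2, n_vol), 1)
    tr[seq(jump_at, n_vol), 1] <- tr[seq(jump_at, n_vol), 1] + 2.6
  }
  tibble::tibble(
    participant = as.integer(participant), run = as.integer(run),
    volume = seq_len(n_vol) - 1L,
    tx = tr[, 1], ty = tr[, 2], tz = tr[, 3],
    rx = ro[, 1], ry = ro[, 2], rz = ro[, 3]
  )
}

#' Simulate judgment-phase button responses
#'
#' @param trial_table trial table (any number of participants).
#' @param p_correct probability an answered trial is correct.
#' @param p_unanswered probability a trial goes unanswered.
#' @param seed integer seed, or `NULL`.
#' @return tibble: trial table columns plus `answered` and `correct`
#'   (`NA` for unanswered trials).
#' @export
simulate_behavior <- function(trial_table, p_correct = 0.95,
                              p_unanswered = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trial_table)
  answered <- stats::runif(n) >= p_unanswered
  correct <- ifelse(answered, stats::runif(n) < p_correct, NA)
  tibble::tibble(
    trial_table[, c("participant", "run", "trial", "condition", "orientation")],
    answered = answered, correct = correct
  )
}

# Everything belonging to one participant, drawn from the current RNG
# state: trial table, ROI matrices, motion, behavior.
.simulate_participant <- function(design, truth, participant,
                                  contaminated_runs = integer(0),
                                  p_correct = 0.95, p_unanswered = 0.02) {
  trials <- build_trial_table(design, seed = NULL, participant = participant)
  data <- lapply(seq_len(design$n_runs), function(r) {
    trials_run <- trials[trials$run == r, ]
    universal <- .universal_course(design, trials_run, truth)
    stats::setNames(lapply(truth$roi_names, function(roi) {
      simulate_roi_run(design, trials_run, truth, roi, universal = universal)
    }), truth$roi_names)
  })
  motion <- dplyr::bind_rows(lapply(seq_len(design$n_runs), function(r) {
    .simulate_motion_run(design, participant, r, r %in% contaminated_runs)
  }))
  behavior <- simulate_behavior(trials, p_correct, p_unanswered)
  list(trials = trials, data = data, motion = motion, behavior = behavior)
}

#' Simulate a full multi-participant dataset
#'
#' Per-participant seeds are derived from the master seed as
#' `seed + participant` (participants indexed 1..n), so any participant
#' can be regenerated in isolation.
#'
#' @param design a `grasp_design`.
#' @param truth a `ground_truth`.
#' @param seed master integer seed.
#' @param contaminated_runs run indices with excessive motion (every
#'   participant).
#' @param p_correct,p_unanswered behavioral response probabilities.
#' @return object of class `grasp_dataset`: `design`, `truth`, `trials`
#'   (all participants), `data[[participant]][[run]][[roi]]`
#'   (`roi_timeseries`), `motion`, `behavior`, `seed`.
#' @export
simulate_dataset <- function(design, truth, seed = 1,
                             contaminated_runs = integer(0),
                             p_correct = 0.95, p_unanswered = 0.02) {
  parts <- lapply(seq_len(design$n_participants), function(p) {
    set.seed(seed + p)
    .simulate_participant(
      design, truth, p, contaminated_runs, p_correct, p_unanswered
    )
  })
  structure(
    list(
      design = design,
      truth = truth,
      trials = dplyr::bind_rows(lapply(parts, `[[`, "trials")),
      data = lapply(parts, `[[`, "data"),
      motion = dplyr::bind_rows(lapply(parts, `[[`, "motion")),
      behavior = dplyr::bind_rows(lapply(parts, `[[`, "behavior")),
      seed = seed
    ),
    class = "grasp_dataset"
  )
}

#' @export
print.grasp_dataset <- function(x, ...) {
  cat(
    "Synthetic dataset:", length(x$data), "participants x",
    x$design$n_runs, "runs x", length(x$truth$roi_names), "ROIs (",
    length(x$data) * x$design$n_runs * length(x$truth$roi_names),
    "matrices ), scenario '", x$truth$scenario, "'\n"
  )
  invisible(x)
}
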