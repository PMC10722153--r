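#' Exclude runs with excessive head motion
#'
#' A run is excluded iff its maximum absolute translation exceeds
#' `translation_mm` or its maximum absolute rotation exceeds
#' `rotation_deg` (strict inequalities: values exactly at threshold are
#' retained).
#'
#' @param motion motion tibble as produced by [simulate_motion()].
#' @param translation_mm translation threshold, mm.
#' @param rotation_deg rotation threshold, degrees.
#' @return named list: participant id -> integer vector of retained runs.
#' @export
exclude_runs <- function(motion, translation_mm = 2, rotation_deg = 2) {
  split_pr <- split(motion, list(motion$participant, motion$run), drop = TRUE)
  keep <- lapply(split_pr, function(d) {
    max_t <- max(abs(c(d$tx, d$ty, d$tz)))
    max_r <- max(abs(c(d$rx, d$ry, d$rz)))
    data.frame(
      participant = d$participant[1], run = d$run[1],
      retained = !(max_t > translation_mm || max_r > rotation_deg)
    )
  })
  keep <- do.call(rbind, keep)
  out <- lapply(split(keep, keep$participant), function(d) {
    sort(d$run[d$retained])
  })
  short <- names(out)[vapply(out, length, 1L) < 2]
  if (length(short)) {
    stop(
      "participant(s) ", paste(short, collapse = ", "),
      " retain fewer than 2 runs; leave-one-run-out is undefined"
    )
  }
  out
}

#' Baseline volume indices of a run
#'
#' Baseline is the lead-in block, the final volume of each inter-trial
#' interval, and any trailing volumes after the last trial.
#'
#' @param design a `grasp_design`.
#' @return 0-based volume indices.
#' @export
baseline_volumes <- function(design) {
  trial_vols <- trial_duration_seconds(design) / design$tr_seconds
  lead <- design$lead_in_volumes
  iti_last <- lead + seq_len(design$trials_per_run) * trial_vols - 1
  tail_start <- lead + design$trials_per_run * trial_vols
  tail_vols <- if (tail_start < design$volumes_per_run) {
    seq(tail_start, design$volumes_per_run - 1)
  } else {
    integer(0)
  }
  as.integer(c(seq_len(lead) - 1, iti_last, tail_vols))
}

#' Remove slow polynomial drift from a run's voxel time series
#'
#' Per voxel, the projection onto centered orthogonal polynomials of
#' the given order is subtracted; the voxel mean is preserved. Without
#' this step, slow scanner drift gives every trial a shared voxel-wise
#' offset across its phases, which a high-dimensional classifier can
#' exploit when training and testing on different phases of the same
#' trials (cross-phase transfer), inflating null accuracy above chance.
#'
#' @param ts a `roi_timeseries`.
#' @param order polynomial order (2 = linear + quadratic).
#' @return the detrended `roi_timeseries`.
#' @export
detrend_run <- function(ts, order = 2) {
  n_vol <- ncol(ts$matrix)
  basis <- stats::poly(seq_len(n_vol), degree = order)  # orthonormal, centered
  ts$matrix <- ts$matrix - (ts$matrix %*% basis) %*% t(basis)
  ts
}

#' Percent signal change of a phase relative to baseline
#'
#' For every trial the `lag_volumes` hemodynamic lag is applied to the
#' phase-onset volume and the next three volumes starting there are
#' averaged; PSC is `100 * (phase mean - baseline mean) / baseline mean`
#' per voxel and event, averaged over voxels and events.
#'
#' @param ts a `roi_timeseries`.
#' @param trials_run trial-table rows for the same run.
#' @param phase phase name.
#' @param design a `grasp_design`.
#' @param lag_volumes hemodynamic lag in volumes (3 volumes = 6 s).
#' @param conditions optional condition subset.
#' @return object of class `psc_result` with fields `roi`, `participant`,
#'   `contrast`, `value`.
#' @export
percent_signal_change <- function(ts, trials_run, phase, design,
                                  lag_volumes = 3, conditions = NULL) {
  if (!is.null(conditions)) {
    trials_run <- trials_run[trials_run$condition %in% conditions, ]
  }
  if (!nrow(trials_run)) stop("no trials left for PSC")
  m <- ts$matrix
  bl <- rowMeans(m[, baseline_volumes(design) + 1, drop = FALSE])
  if (any(bl <= 0)) stop("baseline mean must be positive for PSC")
  onset_vols <- phase_volume_index(trials_run$onset, phase, design)
  windows <- lapply(onset_vols, function(v) {
    idx <- v + lag_volumes + 0:2
    if (any(idx >= design$volumes_per_run)) {
      stop("PSC window exceeds run length at onset volume ", v)
    }
    idx + 1
  })
  psc_events <- vapply(windows, function(idx) {
    mean(100 * (rowMeans(m[, idx, drop = FALSE]) - bl) / bl)
  }, numeric(1))
  structure(
    list(
      roi = ts$roi, participant = ts$participant,
      contrast = paste0(phase, if (!is.null(conditions)) {
        paste0("[", paste(conditions, collapse = "+"), "]")
      } else "", " vs baseline"),
      value = mean(psc_events)
    ),
    class = "psc_result"
  )
}

#' Per-voxel stimulus-versus-baseline contrast scores
#'
#' Welch two-sample t statistic, per voxel, of the lagged
#' instruction-phase (stimulus) volumes pooled over all conditions and
#' both orientations against the baseline volumes, pooled over runs.
#' Pooling over orientations keeps the score orthogonal to the decoded
#' labels. Zero-variance voxels score 0 with a warning.
#'
#' @param ts_list list of `roi_timeseries`, one per retained run.
#' @param trials_by_run list of trial-table subsets matching `ts_list`.
#' @param design a `grasp_design`.
#' @param lag_volumes hemodynamic lag in volumes.
#' @return numeric vector of per-voxel scores.
#' @export
selection_contrast <- function(ts_list, trials_by_run, design,
                               lag_volumes = 3) {
  stopifnot(length(ts_list) >= 2, length(ts_list) == length(trials_by_run))
  stim_cols <- list()
  base_cols <- list()
  bl_idx <- baseline_volumes(design) + 1
  for (k in seq_along(ts_list)) {
    m <- ts_list[[k]]$matrix
    onset_vols <- phase_volume_index(
      trials_by_run[[k]]$onset, "instruction", design
    )
    idx <- unique(as.vector(outer(onset_vols + lag_volumes, 0:2, `+`))) + 1
    stim_cols[[k]] <- m[, idx[idx <= ncol(m)], drop = FALSE]
    base_cols[[k]] <- m[, bl_idx, drop = FALSE]
  }
  stim <- do.call(cbind, stim_cols)
  base <- do.call(cbind, base_cols)
  n1 <- ncol(stim)
  n0 <- ncol(base)
  m1 <- rowMeans(stim)
  m0 <- rowMeans(base)
  v1 <- rowSums((stim - m1)^2) / (n1 - 1)
  v0 <- rowSums((base - m0)^2) / (n0 - 1)
  se <- sqrt(v1 / n1 + v0 / n0)
  score <- (m1 - m0) / se
  flat <- se == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance voxel(s) scored 0")
    score[flat] <- 0
  }
  score
}

#' Select the top-k voxels by contrast score
#'
#' Ties at the rank-`k` boundary are broken by ascending voxel id, so
#' the selection is deterministic. ROIs with fewer than `k` voxels keep
#' all voxels.
#'
#' @param scores per-voxel contrast scores.
#' @param k maximum number of voxels to keep.
#' @param voxel_ids voxel identifiers aligned with `scores`.
#' @param roi,participant bookkeeping fields carried on the result.
#' @return object of class `voxel_selection`: `voxel_ids` (ascending),
#'   `scores` (aligned), `roi`, `participant`.
#' @export
select_voxels <- function(scores, k = 250, voxel_ids = seq_along(scores),
                          roi = NA_character_, participant = NA_integer_) {
  if (!length(scores)) stop("empty ROI: no voxels to select")
  if (any(!is.finite(scores))) stop("contrast scores must be finite")
  ord <- order(-scores, voxel_ids)
  take <- ord[seq_len(min(k, length(scores)))]
  take <- take[order(voxel_ids[take])]
  structure(
    list(
      voxel_ids = voxel_ids[take], scores = scores[take],
      roi = roi, participant = participant
    ),
    class = "voxel_selection"
  )
}

#' Extract one pattern sample per trial for a phase
#'
#' Instruction and judgment samples are the single volume 4 s after the
#' phase onset (onset volume + 2 at TR 2 s); action samples average the
#' two volumes 8 s and 10 s after the onset (onset volume + 4 and + 5),
#' accommodating the 4 s movement time. Values are raw (z-scoring happens
#' per cross-validation fold).
#'
#' @param ts a `roi_timeseries`.
#' @param selection a `voxel_selection` for the same ROI/participant.
#' @param trials_run trial-table rows for the run.
#' @param phase one of `instruction`, `action`, `judgment`.
#' @param design a `grasp_design`.
#' @return object of class `pattern_set`: feature matrix `x` (trials x
#'   selected voxels) and `meta` tibble (`participant`, `run`, `trial`,
#'   `condition`, `orientation`, `phase`).
#' @export
extract_patterns <- function(ts, selection, trials_run, phase, design) {
  if (!phase %in% c("instruction", "action", "judgment")) {
    stop("patterns are defined for the instruction, action and judgment phases")
  }
  onset_vols <- phase_volume_index(trials_run$onset, phase, design)
  pick <- if (phase == "action") 4:5 else 2
  bad <- outer(onset_vols, pick, `+`) >= design$volumes_per_run
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)[1]
    stop(
      "pattern window exceeds run length for trial ",
      trials_run$trial[i], " of run ", trials_run$run[i]
    )
  }
  m <- ts$matrix[selection$voxel_ids, , drop = FALSE]
  x <- if (length(pick) == 1) {
    t(m[, onset_vols + pick + 1, drop = FALSE])
  } else {
    (t(m[, onset_vols + pick[1] + 1, drop = FALSE]) +
       t(m[, onset_vols + pick[2] + 1, drop = FALSE])) / 2
  }
  structure(
    list(
      x = x,
      meta = tibble::new_tibble(list(
        participant = trials_run$participant,
        run = trials_run$run,
        trial = trials_run$trial,
        condition = trials_run$condition,
        orientation = trials_run$orientation,
        phase = rep(phase, nrow(trials_run))
      ), nrow = nrow(trials_run)),
      roi = ts$roi
    ),
    class = "pattern_set"
  )
}

#' Combine pattern sets sample-wise
#' @param ... `pattern_set` objects with identical feature spaces.
#' @export
bind_patterns <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
        !inherits(sets[[1]], "pattern_set")) {
    sets <- sets[[1]]
  }
  widths <- vapply(sets, function(s) ncol(s$x), 1L)
  if (length(unique(widths)) != 1) stop("feature-length mismatch")
  structure(
    list(
      x = do.call(rbind, lapply(sets, `[[`, "x")),
      meta = dplyr::bind_rows(lapply(sets, `[[`, "meta")),
      roi = sets[[1]]$roi
    ),
    class = "pattern_set"
  )
}

#' Subset a pattern set by metadata
#' @param set a `pattern_set`.
#' @param keep logical vector over samples.
#' @export
filter_patterns <- function(set, keep) {
  structure(
    list(x = set$x[keep, , drop = FALSE], meta = set$meta[keep, ],
         roi = set$roi),
    class = "pattern_set"
  )
}

#' Fold-wise z-scoring
#'
#' Per-feature mean and standard deviation are computed on the training
#' samples only and applied to both matrices; features with zero
#' training SD become 0 everywhere (no division error, no leakage).
#'
#' @param train,test feature matrices (samples x features); `test` may
#'   be `NULL`.
#' @return list with normalized `train` and `test`.
#' @export
zscore_fold <- function(train, test = NULL) {
  stopifnot(nrow(train) >= 1)
  n <- nrow(train)
  mu <- colMeans(train)
  sd <- if (n > 1) {
    sqrt(pmax(colSums(train^2) - n * mu^2, 0) / (n - 1))
  } else {
    rep(0, ncol(train))
  }
  flat <- sd == 0 | !is.finite(sd)
  sd[flat] <- 1
  scale_mat <- function(m) {
    nm <- nrow(m)
    z <- (m - rep(mu, each = nm)) / rep(sd, each = nm)
    z[, flat] <- 0
    z
  }
  list(
    train = scale_mat(train),
    test = if (is.null(test)) NULL else scale_mat(test)
  )
}
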