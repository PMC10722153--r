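#' Write a trial table as a BIDS-style events TSV
#'
#' Columns: `onset`, `duration`, `trial_type`
#' (`condition_orientation`, e.g. `DG_+45`), `run`, `participant`.
#'
#' @param trial_table tibble from [build_trial_table()].
#' @param path output file.
#' @export
write_events_tsv <- function(trial_table, path) {
  out <- data.frame(
    onset = trial_table$onset,
    duration = rep(
      sum(attr(trial_table, "trial_duration") %||% 24),
      nrow(trial_table)
    ),
    trial_type = paste(trial_table$condition, trial_table$orientation,
                       sep = "_"),
    run = trial_table$run,
    participant = trial_table$participant
  )
  utils::write.table(
    out, path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a BIDS-style events TSV into a trial table
#' @param path events TSV file.
#' @return tibble with the [build_trial_table()] columns.
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("onset", "trial_type", "run", "participant")
  if (!all(needed %in% names(d))) {
    stop("events file needs columns: ", paste(needed, collapse = ", "))
  }
  parts <- strsplit(d$trial_type, "_", fixed = TRUE)
  tab <- tibble::tibble(
    participant = as.integer(d$participant),
    run = as.integer(d$run),
    condition = vapply(parts, `[`, "", 1),
    orientation = vapply(parts, function(p) paste(p[-1], collapse = "_"), ""),
    onset = as.numeric(d$onset)
  )
  tab <- tab[order(tab$participant, tab$run, tab$onset), ]
  tab$trial <- stats::ave(
    tab$onset, tab$participant, tab$run, FUN = seq_along
  )
  tab$trial <- as.integer(tab$trial)
  tab[, c("participant", "run", "trial", "condition", "orientation", "onset")]
}

#' Serialize a design to JSON
#' @param design a `grasp_design`.
#' @param path optional output file; omitted returns the JSON string.
#' @export
design_to_json <- function(design, path = NULL) {
  lst <- unclass(design)
  # named atomic vectors serialize as bare arrays; keep the phase names
  lst$phase_durations_seconds <- as.list(lst$phase_durations_seconds)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Rebuild a design from JSON
#' @param json JSON string or file path.
#' @export
design_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json)
  lst$phase_durations_seconds <- unlist(lst$phase_durations_seconds)
  ints <- c(
    "volumes_per_run", "n_runs", "trials_per_run", "n_participants",
    "repetitions_per_setting", "lead_in_volumes"
  )
  for (f in ints) lst[[f]] <- as.integer(lst[[f]])
  build_design(lst)
}

#' Write one ROI matrix as delimited text
#' @param ts a `roi_timeseries`.
#' @param path output TSV (voxels x volumes, no headers).
#' @export
write_roi_matrix <- function(ts, path) {
  utils::write.table(
    ts$matrix, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read one ROI matrix from delimited text
#' @param path TSV file (voxels x volumes).
#' @param participant,run,roi metadata to attach.
#' @export
read_roi_matrix <- function(path, participant = NA_integer_,
                            run = NA_integer_, roi = NA_character_) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  structure(
    list(
      participant = participant, run = run, roi = roi,
      matrix = m, voxel_ids = seq_len(nrow(m))
    ),
    class = "roi_timeseries"
  )
}

#' Write a simulated dataset as plain-text files plus a JSON manifest
#'
#' Layout: `events.tsv` (all participants), `motion.tsv`,
#' `behavior.tsv`, `design.json`, one matrix file per
#' participant/run/ROI under `matrices/`, and `manifest.json` listing
#' them.
#'
#' @param dataset a `grasp_dataset`.
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  write_events_tsv(dataset$trials, file.path(dir, "events.tsv"))
  utils::write.table(dataset$motion, file.path(dir, "motion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  design_to_json(dataset$design, file.path(dir, "design.json"))
  entries <- list()
  for (p in seq_along(dataset$data)) {
    for (r in seq_along(dataset$data[[p]])) {
      for (roi in names(dataset$data[[p]][[r]])) {
        f <- sprintf("matrices/sub-%02d_run-%02d_%s.tsv", p, r, roi)
        write_roi_matrix(dataset$data[[p]][[r]][[roi]], file.path(dir, f))
        entries[[length(entries) + 1]] <- list(
          participant = p, run = r, roi = roi, file = f
        )
      }
    }
  }
  manifest <- list(
    scenario = dataset$truth$scenario, seed = dataset$seed,
    n_participants = length(dataset$data), matrices = entries
  )
  writeLines(
    as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)),
    file.path(dir, "manifest.json")
  )
  invisible(dir)
}

#' Read a dataset written by [write_dataset()] (real-data import hook)
#'
#' Reads per-ROI voxel x time matrices plus the events/motion/behavior
#' tables back into the structures the pipeline consumes. This is also
#' the supported path for real scanner data: provide matrices and a
#' manifest in the same layout.
#'
#' @param dir dataset directory.
#' @return a `grasp_dataset` (without ground truth).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::fromJSON(
    file.path(dir, "manifest.json"), simplifyDataFrame = TRUE
  )
  design <- design_from_json(file.path(dir, "design.json"))
  trials <- read_events_tsv(file.path(dir, "events.tsv"))
  motion <- tibble::as_tibble(
    utils::read.delim(file.path(dir, "motion.tsv"))
  )
  behavior <- tibble::as_tibble(
    utils::read.delim(file.path(dir, "behavior.tsv"))
  )
  mats <- manifest$matrices
  data <- lapply(sort(unique(mats$participant)), function(p) {
    lapply(sort(unique(mats$run[mats$participant == p])), function(r) {
      rows <- mats[mats$participant == p & mats$run == r, ]
      stats::setNames(lapply(seq_len(nrow(rows)), function(i) {
        read_roi_matrix(
          file.path(dir, rows$file[i]),
          participant = p, run = r, roi = rows$roi[i]
        )
      }), rows$roi)
    })
  })
  structure(
    list(
      design = design, truth = NULL, trials = trials, data = data,
      motion = motion, behavior = behavior, seed = manifest$seed
    ),
    class = "grasp_dataset"
  )
}
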