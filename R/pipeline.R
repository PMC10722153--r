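#' Default pipeline configuration
#'
#' A single configuration object drives simulate -> preprocess ->
#' decode -> stats. The transfer-pair default is the six action-phase
#' condition pairs; cross-phase decoding pairs the instruction and
#' action phases within each condition.
#'
#' @param ... fields overriding the defaults.
#' @return a `pipeline_config` list.
#' @export
default_config <- function(...) {
  config <- list(
    scenario = "paper_fig2",
    seed = 1,
    design = list(),
    truth = list(),
    rois = NULL,
    phases = c("instruction", "action", "judgment"),
    analyses = c("same", "transfer", "cross_phase", "psc"),
    transfer_phase = "action",
    transfer_pairs = list(
      c("DG", "AG"), c("DG", "UG"), c("AG", "UG"),
      c("AG", "NG"), c("DG", "NG"), c("UG", "NG")
    ),
    cross_phase_conditions = c("DG", "AG", "NG", "UG"),
    cost = 1,
    chance = 0.5,
    alpha = 0.05,
    q = 0.05,
    fdr_family = "analysis",
    psc_threshold = 5e-4,
    selection_k = 250,
    detrend = TRUE,
    contaminated_runs = integer(0),
    p_correct = 0.95,
    p_unanswered = 0.02,
    output_dir = NULL,
    verbose = TRUE
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
        is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  config[names(overrides)] <- overrides
  class(config) <- "pipeline_config"
  validate_config(config)
}

#' Validate a pipeline configuration
#' @param config a `pipeline_config`.
#' @export
validate_config <- function(config) {
  conds <- c("DG", "AG", "NG", "UG")
  phases <- c("instruction", "action", "judgment")
  if (is.null(config$seed)) stop("a master seed is mandatory")
  if (!all(config$phases %in% phases)) {
    stop("phases must be drawn from: ", paste(phases, collapse = ", "))
  }
  if (!all(unlist(config$transfer_pairs) %in% conds) ||
        !all(config$cross_phase_conditions %in% conds)) {
    stop("condition pairs must be drawn from: ", paste(conds, collapse = ", "))
  }
  if (!all(config$analyses %in% c("same", "transfer", "cross_phase", "psc"))) {
    stop("analyses must be drawn from: same, transfer, cross_phase, psc")
  }
  if (!config$fdr_family %in% c("analysis", "panel")) {
    stop("fdr_family must be 'analysis' or 'panel'")
  }
  invisible(config)
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

# retained runs for a single participant's motion trace
.retained_runs <- function(motion, translation_mm = 2, rotation_deg = 2) {
  ex <- exclude_runs(motion, translation_mm, rotation_deg)
  ex[[as.character(motion$participant[1])]]
}

#' Run the full analysis pipeline
#'
#' Simulates the dataset (participant by participant, so the full
#' voxel-level data never has to be held at once), applies motion-based
#' run exclusion, selects voxels, extracts phase patterns, runs the
#' configured decoding analyses and the univariate percent-signal-change
#' summaries, and computes group-level statistics with FDR correction.
#' Fully deterministic given the configuration.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @return a `pipeline_result` bundle: tibbles `decoding`, `folds`,
#'   `group_stats`, `psc`, `psc_group`, `behavioral`, and a `manifest`
#'   list. Tables are also written as TSV when `config$output_dir` is
#'   set.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  t_start <- Sys.time()
  design <- build_design(config$design)
  truth <- do.call(make_ground_truth, c(
    list(scenario = config$scenario, seed = config$seed, rois = config$rois),
    config$truth
  ))
  .log_stage(
    config$verbose, "simulating scenario '%s' (%d participants, %d ROIs)",
    config$scenario, design$n_participants, length(truth$roi_names)
  )

  need_phases <- unique(c(
    if ("same" %in% config$analyses) config$phases,
    if ("transfer" %in% config$analyses) config$transfer_phase,
    if ("cross_phase" %in% config$analyses) c("instruction", "action")
  ))

  decode_rows <- list()
  psc_rows <- list()
  behavior_all <- list()
  retained_counts <- integer(0)

  for (p in seq_len(design$n_participants)) {
    set.seed(config$seed + p)
    part <- .simulate_participant(
      design, truth, p, config$contaminated_runs,
      config$p_correct, config$p_unanswered
    )
    runs <- .retained_runs(part$motion)
    retained_counts[p] <- length(runs)
    behavior_all[[p]] <- part$behavior

    for (roi in truth$roi_names) {
      ts_list <- lapply(runs, function(r) {
        if (config$detrend) detrend_run(part$data[[r]][[roi]])
        else part$data[[r]][[roi]]
      })
      trials_by_run <- lapply(runs, function(r) {
        part$trials[part$trials$run == r, ]
      })
      scores <- selection_contrast(ts_list, trials_by_run, design)
      sel <- select_voxels(scores, k = config$selection_k,
                           roi = roi, participant = p)
      sets <- lapply(
        stats::setNames(need_phases, need_phases),
        function(ph) {
          bind_patterns(lapply(seq_along(runs), function(k) {
            extract_patterns(ts_list[[k]], sel, trials_by_run[[k]], ph, design)
          }))
        }
      )

      results <- list()
      if ("same" %in% config$analyses) {
        for (ph in config$phases) {
          for (cond in design$conditions) {
            set_c <- filter_patterns(sets[[ph]], sets[[ph]]$meta$condition == cond)
            results[[length(results) + 1]] <- loro_accuracy(set_c, config$cost)
          }
        }
      }
      if ("transfer" %in% config$analyses) {
        ph <- config$transfer_phase
        for (pair in config$transfer_pairs) {
          set_a <- filter_patterns(sets[[ph]], sets[[ph]]$meta$condition == pair[1])
          set_b <- filter_patterns(sets[[ph]], sets[[ph]]$meta$condition == pair[2])
          results[[length(results) + 1]] <-
            transfer_accuracy(set_a, set_b, config$cost)
        }
      }
      if ("cross_phase" %in% config$analyses) {
        for (cond in config$cross_phase_conditions) {
          set_i <- filter_patterns(
            sets[["instruction"]], sets[["instruction"]]$meta$condition == cond
          )
          set_a <- filter_patterns(
            sets[["action"]], sets[["action"]]$meta$condition == cond
          )
          results[[length(results) + 1]] <-
            cross_phase_accuracy(set_i, set_a, config$cost)
        }
      }
      decode_rows[[length(decode_rows) + 1]] <- results

      psc_specs <- if (!"psc" %in% config$analyses) list() else list(
        list(phase = "instruction", conditions = NULL, name = "stimuli"),
        list(phase = "action", conditions = NULL, name = "grasping"),
        list(phase = "judgment", conditions = NULL, name = "judgment"),
        list(phase = "instruction", conditions = "UG", name = "UG_instruction"),
        list(phase = "action", conditions = "NG", name = "NG_action")
      )
      for (spec in psc_specs) {
        # runs without a trial of the restricted condition contribute
        # nothing to that contrast
        vals <- vapply(seq_along(runs), function(k) {
          tr <- trials_by_run[[k]]
          if (!is.null(spec$conditions) &&
                !any(tr$condition %in% spec$conditions)) {
            return(NA_real_)
          }
          percent_signal_change(
            ts_list[[k]], tr, spec$phase, design,
            conditions = spec$conditions
          )$value
        }, numeric(1))
        psc_rows[[length(psc_rows) + 1]] <- tibble::tibble(
          participant = p, roi = roi, contrast = spec$name,
          psc = mean(vals, na.rm = TRUE)
        )
      }
    }
    .log_stage(
      config$verbose, "participant %d: %d runs retained, %d ROIs decoded",
      p, length(runs), length(truth$roi_names)
    )
  }

  all_results <- unlist(decode_rows, recursive = FALSE)
  decoding <- tibble::new_tibble(list(
    participant = vapply(all_results, `[[`, 0L, "participant"),
    roi = vapply(all_results, `[[`, "", "roi"),
    analysis = vapply(all_results, `[[`, "", "kind"),
    phase = vapply(all_results, `[[`, "", "phase"),
    condition = vapply(all_results, `[[`, "", "condition"),
    accuracy = vapply(all_results, `[[`, 0, "accuracy"),
    n_folds = vapply(all_results, `[[`, 0L, "n_folds")
  ), nrow = length(all_results))
  fold_counts <- vapply(all_results, `[[`, 0L, "n_folds")
  folds <- tibble::new_tibble(list(
    participant = rep(decoding$participant, fold_counts),
    roi = rep(decoding$roi, fold_counts),
    analysis = rep(decoding$analysis, fold_counts),
    phase = rep(decoding$phase, fold_counts),
    condition = rep(decoding$condition, fold_counts),
    fold = unlist(lapply(fold_counts, seq_len)),
    accuracy = unname(unlist(lapply(all_results, `[[`, "fold_accuracies")))
  ), nrow = sum(fold_counts))
  psc <- dplyr::bind_rows(psc_rows)
  behavior <- dplyr::bind_rows(behavior_all)

  group_stats <- if (nrow(decoding)) {
    group_decoding_stats(
      decoding, chance = config$chance, alpha = config$alpha, q = config$q,
      family = config$fdr_family
    )
  } else {
    tibble::tibble(
      analysis = character(), phase = character(), condition = character(),
      roi = character(), mean_accuracy = numeric(), n = integer(),
      t = numeric(), df = numeric(), p = numeric(), p_adj = numeric(),
      sig_uncorrected = logical(), sig_fdr = logical()
    )
  }
  psc_group <- if (nrow(psc)) {
    dplyr::summarise(
      dplyr::group_by(psc, roi, contrast),
      mean_psc = mean(psc),
      t = psc_group_test(psc, config$psc_threshold)$t,
      p = psc_group_test(psc, config$psc_threshold)$p,
      significant = psc_group_test(psc, config$psc_threshold)$significant,
      n = dplyr::n(),
      .groups = "drop"
    )
  } else {
    tibble::tibble(
      roi = character(), contrast = character(), mean_psc = numeric(),
      t = numeric(), p = numeric(), significant = logical(), n = integer()
    )
  }
  behavioral <- behavioral_accuracy(behavior)

  manifest <- list(
    package_version = as.character(utils::packageVersion("graspmvpa")),
    seed = config$seed,
    scenario = config$scenario,
    config = config[setdiff(names(config), c("output_dir", "verbose"))],
    config_hash = .config_hash(config),
    runs_retained = retained_counts,
    n_decoding_cells = nrow(group_stats),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  bundle <- structure(
    list(
      decoding = decoding, folds = folds, group_stats = group_stats,
      psc = psc, psc_group = psc_group, behavioral = behavioral,
      manifest = manifest
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) {
    write_results(bundle, config$output_dir)
  }
  .log_stage(config$verbose, "done in %.1f s", manifest$elapsed_seconds)
  bundle
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(
    config[setdiff(names(config), c("output_dir", "verbose"))],
    auto_unbox = TRUE, digits = NA, force = TRUE
  )), f)
  unname(tools::md5sum(f))
}

#' Write a result bundle as tidy TSV files plus a JSON manifest
#' @param bundle a `pipeline_result`.
#' @param dir output directory.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("decoding", "folds", "group_stats", "psc", "psc_group",
              "behavioral")
  for (tb in tables) {
    utils::write.table(
      bundle[[tb]], file.path(dir, paste0(tb, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  writeLines(
    as.character(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE,
                                  digits = NA, force = TRUE)),
    file.path(dir, "manifest.json")
  )
  writeLines(make_report(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Render a plain-text summary of a result bundle
#'
#' One panel per (analysis kind, phase): rows are ROIs, columns are
#' conditions (or condition pairs), entries are group mean accuracies in
#' percent; `*` marks cells significant after FDR correction. Every
#' number is read from the serialized group table — nothing is
#' recomputed at render time.
#'
#' @param bundle a `pipeline_result`.
#' @return character vector of report lines.
#' @export
make_report <- function(bundle) {
  gs <- bundle$group_stats
  lines <- c(
    "ROI-based orientation decoding summary",
    sprintf("chance level: 50%%; * = FDR-significant (q <= 0.05)"),
    ""
  )
  panels <- unique(gs[, c("analysis", "phase")])
  if (!nrow(panels)) {
    warning("no decoding panels in bundle")
  }
  for (i in seq_len(nrow(panels))) {
    panel <- gs[gs$analysis == panels$analysis[i] &
                  gs$phase == panels$phase[i], ]
    conds <- unique(panel$condition)
    rois <- unique(panel$roi)
    lines <- c(lines, sprintf(
      "-- %s decoding, %s phase --", panels$analysis[i], panels$phase[i]
    ))
    header <- sprintf("%-6s %s", "ROI",
                      paste(sprintf("%9s", conds), collapse = " "))
    lines <- c(lines, header)
    for (roi in rois) {
      cells <- vapply(conds, function(cd) {
        row <- panel[panel$roi == roi & panel$condition == cd, ]
        if (!nrow(row)) return(sprintf("%9s", "-"))
        sprintf(
          "%8.1f%s", 100 * row$mean_accuracy[1],
          ifelse(row$sig_fdr[1], "*", " ")
        )
      }, character(1))
      lines <- c(lines, sprintf("%-6s %s", roi, paste(cells, collapse = " ")))
    }
    lines <- c(lines, "")
  }
  if (nrow(bundle$psc_group)) {
    lines <- c(lines, "-- percent signal change (group mean, * = significant) --")
    pg <- bundle$psc_group
    for (ct in unique(pg$contrast)) {
      sub <- pg[pg$contrast == ct, ]
      lines <- c(lines, sprintf(
        "%-15s %s", ct,
        paste(sprintf("%s=%.2f%s", sub$roi, sub$mean_psc,
                      ifelse(sub$significant, "*", "")), collapse = " ")
      ))
    }
    lines <- c(lines, "")
  }
  if (nrow(bundle$behavioral)) {
    lines <- c(lines, sprintf(
      "behavioral judgment accuracy: mean %.3f (n = %d participants)",
      mean(bundle$behavioral$accuracy, na.rm = TRUE),
      nrow(bundle$behavioral)
    ))
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(
    "Pipeline result:", nrow(x$group_stats), "group cells,",
    nrow(x$decoding), "participant-level accuracies\n"
  )
  invisible(x)
}
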