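#!/usr/bin/env Rscript
# Stage 2 — run exclusion, univariate summaries, voxel selection.
#
# Applies the motion-based run-exclusion rule (> 2 mm translation or
# > 2 degrees rotation excludes the run), computes percent-signal-change
# summaries per ROI and contrast, and selects the top-250
# stimulus-responsive voxels per participant and ROI. Pattern matrices
# for the three trial phases are extracted once here and reused by the
# decoding stage.

suppressMessages(library(graspmvpa))

dataset <- readRDS("scratch/dataset.rds")
design <- dataset$design
truth <- dataset$truth

retained <- exclude_runs(dataset$motion)
message("Runs retained per participant: ",
        paste(vapply(retained, length, 1L), collapse = " "))

psc_rows <- list()
patterns <- list()
for (p in seq_along(dataset$data)) {
  runs <- retained[[as.character(p)]]
  trials_p <- dataset$trials[dataset$trials$participant == p, ]
  for (roi in truth$roi_names) {
    ts_list <- lapply(runs, function(r) {
      detrend_run(dataset$data[[p]][[r]][[roi]])
    })
    tbr <- lapply(runs, function(r) trials_p[trials_p$run == r, ])
    sel <- select_voxels(selection_contrast(ts_list, tbr, design),
                         k = 250, roi = roi, participant = p)
    for (phase in c("instruction", "action", "judgment")) {
      patterns[[paste(p, roi, phase, sep = ".")]] <-
        bind_patterns(lapply(seq_along(runs), function(k) {
          extract_patterns(ts_list[[k]], sel, tbr[[k]], phase, design)
        }))
      vals <- vapply(seq_along(runs), function(k) {
        percent_signal_change(ts_list[[k]], tbr[[k]], phase, design)$value
      }, numeric(1))
      psc_rows[[length(psc_rows) + 1]] <- tibble::tibble(
        participant = p, roi = roi, contrast = phase, psc = mean(vals)
      )
    }
  }
  message("participant ", p, ": ", length(runs), " runs, ",
          length(truth$roi_names), " ROIs preprocessed")
}

psc <- dplyr::bind_rows(psc_rows)
utils::write.table(psc, "results/psc.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
saveRDS(list(patterns = patterns, retained = retained),
        "scratch/patterns.rds")

psc_summary <- dplyr::summarise(
  dplyr::group_by(psc, roi, contrast), mean_psc = mean(psc),
  .groups = "drop"
)
message("Mean PSC by ROI (stimulus phase):")
stim <- psc_summary[psc_summary$contrast == "instruction", ]
message(paste(sprintf("  %-6s %.2f%%", stim$roi, stim$mean_psc),
              collapse = "\n"))
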