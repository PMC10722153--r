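#!/usr/bin/env Rscript
# Stage 3 — multivoxel orientation decoding.
#
# Same-type decoding: leave-one-run-out cross-validated classification
# of the two object orientations within each action condition, per ROI,
# phase and participant. Transfer-type decoding: train on one action
# condition, test on another (six pairs in the action phase), both
# directions averaged. Cross-phase decoding: train on instruction-phase
# patterns, test on action-phase patterns of the same condition, and
# vice versa.

suppressMessages(library(graspmvpa))

dataset <- readRDS("scratch/dataset.rds")
pre <- readRDS("scratch/patterns.rds")
design <- dataset$design
truth <- dataset$truth
conds <- design$conditions
pairs <- list(c("DG", "AG"), c("DG", "UG"), c("AG", "UG"),
              c("AG", "NG"), c("DG", "NG"), c("UG", "NG"))

get_set <- function(p, roi, phase, cond = NULL) {
  s <- pre$patterns[[paste(p, roi, phase, sep = ".")]]
  if (is.null(cond)) s else filter_patterns(s, s$meta$condition == cond)
}

results <- list()
for (p in seq_along(dataset$data)) {
  for (roi in truth$roi_names) {
    for (phase in c("instruction", "action", "judgment")) {
      for (cond in conds) {
        results[[length(results) + 1]] <-
          loro_accuracy(get_set(p, roi, phase, cond))
      }
    }
    for (pair in pairs) {
      results[[length(results) + 1]] <- transfer_accuracy(
        get_set(p, roi, "action", pair[1]),
        get_set(p, roi, "action", pair[2])
      )
    }
    for (cond in conds) {
      results[[length(results) + 1]] <- cross_phase_accuracy(
        get_set(p, roi, "instruction", cond),
        get_set(p, roi, "action", cond)
      )
    }
  }
  message("participant ", p, " decoded")
}

decoding <- dplyr::bind_rows(lapply(results, function(r) {
  tibble::tibble(
    participant = r$participant, roi = r$roi, analysis = r$kind,
    phase = r$phase, condition = r$condition, accuracy = r$accuracy,
    n_folds = r$n_folds
  )
}))
utils::write.table(decoding, "results/decoding.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

summary <- dplyr::summarise(
  dplyr::group_by(decoding, analysis, phase),
  mean_accuracy = mean(accuracy), .groups = "drop"
)
message("Mean decoding accuracy by analysis and phase:")
message(paste(sprintf("  %-12s %-20s %.3f", summary$analysis,
                      summary$phase, summary$mean_accuracy),
              collapse = "\n"))
message("Per-participant table: results/decoding.tsv (",
        nrow(decoding), " rows).")
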