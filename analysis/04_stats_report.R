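#!/usr/bin/env Rscript
# Stage 4 — group-level inference and the summary report.
#
# One-sample two-tailed t tests of per-participant decoding accuracies
# against the 50% chance level, with Benjamini-Hochberg FDR correction
# applied within each (analysis kind, phase) panel, plus the
# percent-signal-change group tests against zero. Renders the panel
# tables (ROIs x conditions, '*' marking FDR-significant cells) and,
# when ggplot2 is available, bar figures of the group means.

suppressMessages(library(graspmvpa))

decoding <- tibble::as_tibble(
  utils::read.delim("results/decoding.tsv", stringsAsFactors = FALSE)
)
psc <- tibble::as_tibble(utils::read.delim("results/psc.tsv"))

group_stats <- group_decoding_stats(decoding)
utils::write.table(group_stats, "results/group_stats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

psc_group <- dplyr::summarise(
  dplyr::group_by(psc, roi, contrast),
  mean_psc = mean(psc),
  t = psc_group_test(psc)$t,
  p = psc_group_test(psc)$p,
  significant = psc_group_test(psc)$significant,
  n = dplyr::n(),
  .groups = "drop"
)
utils::write.table(psc_group, "results/psc_group.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

behavioral <- tibble::as_tibble(
  utils::read.delim("results/behavioral_accuracy.tsv")
)
bundle <- structure(
  list(decoding = decoding, folds = tibble::tibble(),
       group_stats = group_stats, psc = psc, psc_group = psc_group,
       behavioral = behavioral, manifest = list()),
  class = "pipeline_result"
)
report <- make_report(bundle)
writeLines(report, "results/report.txt")
message(paste(report, collapse = "\n"))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  same <- group_stats[group_stats$analysis == "same", ]
  same$roi <- factor(same$roi, levels = unique(same$roi))
  fig <- ggplot(same, aes(roi, mean_accuracy, fill = condition)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    geom_text(
      aes(label = ifelse(sig_fdr, "*", ""), group = condition),
      position = position_dodge(0.8), vjust = -0.2, size = 5
    ) +
    facet_wrap(~phase, ncol = 1) +
    coord_cartesian(ylim = c(0.3, 1.05)) +
    labs(x = NULL, y = "decoding accuracy",
         title = "Same-type orientation decoding by ROI and condition",
         subtitle = "* = FDR-significant vs 50% chance (q <= 0.05)") +
    theme_minimal()
  ggsave("results/fig_same_type.pdf", fig, width = 8, height = 9)
  message("Figure: results/fig_same_type.pdf")
}
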