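#' One-sample t test across participants
#'
#' Two-tailed one-sample t test of per-participant scalars against a
#' null mean (chance level for decoding, 0 for percent signal change).
#' A zero-variance sample equal to the null gives `t = 0, p = 1`; a
#' zero-variance sample away from the null is an error (t undefined).
#'
#' @param values per-participant scalars.
#' @param null_mean null-hypothesis mean.
#' @return list with `t`, `p`, `df`, `mean`, `n`.
#' @export
group_ttest <- function(values, null_mean) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("group test needs at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (stats::sd(values) == 0) {
    if (values[1] == null_mean) {
      return(list(
        t = 0, p = 1, df = length(values) - 1,
        mean = values[1], n = length(values)
      ))
    }
    stop("zero variance with mean != null: t statistic undefined")
  }
  ht <- stats::t.test(values, mu = null_mean, alternative = "two.sided")
  list(
    t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
    mean = mean(values), n = length(values)
  )
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure at level `q`: adjusted p values are
#' `p.adjust(p, "BH")`; a test is significant when its adjusted value is
#' at most `q`.
#'
#' @param p_values vector of p values in `[0, 1]`.
#' @param q FDR level.
#' @return list with logical `significant` and numeric `adjusted`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(significant = adjusted <= q, adjusted = adjusted)
}

#' Group test of percent signal change against zero
#'
#' @param values per-participant PSC values.
#' @param threshold significance threshold on the p value.
#' @return list with `mean`, `t`, `p`, `df`, `n`, `significant`.
#' @export
psc_group_test <- function(values, threshold = 5e-4) {
  res <- group_ttest(values, null_mean = 0)
  res$significant <- res$p < threshold
  res
}

#' Behavioral judgment accuracy per participant
#'
#' Proportion of correct responses among answered trials; unanswered
#' trials are excluded from the denominator. Participants with no
#' answered trials are reported as `NA`.
#'
#' @param behavior tibble from [simulate_behavior()] (columns
#'   `participant`, `answered`, `correct`).
#' @return tibble: `participant`, `n_answered`, `n_correct`, `accuracy`.
#' @export
behavioral_accuracy <- function(behavior) {
  dplyr::summarise(
    dplyr::group_by(behavior, participant),
    n_answered = sum(answered),
    n_correct = sum(correct, na.rm = TRUE),
    accuracy = ifelse(n_answered > 0, n_correct / n_answered, NA_real_),
    .groups = "drop"
  )
}

# group_ttest with a defined limit for saturated cells: identical
# accuracies away from chance (e.g. every participant at 1.0) give
# t = +/-Inf, p = 0 instead of an error, so pipelines with very strong
# signal still produce a table.
.cell_test <- function(values, null_mean) {
  if (length(values) >= 2 && stats::sd(values) == 0 &&
        values[1] != null_mean) {
    return(list(
      t = sign(values[1] - null_mean) * Inf, p = 0,
      df = length(values) - 1, mean = values[1], n = length(values)
    ))
  }
  group_ttest(values, null_mean)
}

#' Group-level decoding inference table
#'
#' One-sample t tests of per-participant accuracies against chance
#' (50%), with Benjamini-Hochberg FDR correction over the number of
#' ROIs times the number of tests of one analysis kind. With
#' `family = "analysis"` (default) the correction family is all cells
#' of an analysis kind jointly — e.g. for same-type decoding the nine
#' ROIs crossed with every condition and phase tested; with
#' `family = "panel"` correction is applied per (analysis kind, phase)
#' results panel instead.
#'
#' @param decoding tidy tibble of per-participant accuracies with
#'   columns `participant`, `roi`, `analysis`, `phase`, `condition`,
#'   `accuracy`.
#' @param chance chance level.
#' @param alpha uncorrected significance threshold.
#' @param q FDR level.
#' @param family correction family scope, `"analysis"` or `"panel"`.
#' @return tibble: one row per ROI x condition x phase x analysis with
#'   `mean_accuracy`, `t`, `df`, `p`, `p_adj`, `sig_uncorrected`,
#'   `sig_fdr`, `n`.
#' @export
group_decoding_stats <- function(decoding, chance = 0.5, alpha = 0.05,
                                 q = 0.05, family = c("analysis", "panel")) {
  family <- match.arg(family)
  per_cell <- dplyr::summarise(
    dplyr::group_by(decoding, analysis, phase, condition, roi),
    mean_accuracy = mean(accuracy),
    stats = list(.cell_test(accuracy, chance)),
    n = dplyr::n(),
    .groups = "drop"
  )
  per_cell$t <- vapply(per_cell$stats, `[[`, numeric(1), "t")
  per_cell$df <- vapply(per_cell$stats, `[[`, numeric(1), "df")
  per_cell$p <- vapply(per_cell$stats, `[[`, numeric(1), "p")
  per_cell$stats <- NULL
  grouped <- if (family == "analysis") {
    dplyr::group_by(per_cell, analysis)
  } else {
    dplyr::group_by(per_cell, analysis, phase)
  }
  out <- dplyr::mutate(
    grouped,
    p_adj = fdr_bh(p, q)$adjusted,
    sig_uncorrected = p < alpha,
    sig_fdr = fdr_bh(p, q)$significant
  )
  dplyr::ungroup(out)
}
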