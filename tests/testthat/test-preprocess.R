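make_motion_row <- function(participant, run, n_vol, tmax = 0, rmax = 0) {
  tibble::tibble(
    participant = participant, run = run, volume = seq_len(n_vol) - 1L,
    tx = c(0, rep(tmax, n_vol - 1)), ty = 0, tz = 0,
    rx = c(0, rep(rmax, n_vol - 1)), ry = 0, rz = 0
  )
}

test_that("run exclusion applies strict 2 mm / 2 degree disjunction", {
  m <- dplyr::bind_rows(
    make_motion_row(1, 1, 10, tmax = 1.9, rmax = 1.5),  # retained
    make_motion_row(1, 2, 10, tmax = 2.1, rmax = 0.5),  # excluded: trans
    make_motion_row(1, 3, 10, tmax = 0.1, rmax = 2.4),  # excluded: rot
    make_motion_row(1, 4, 10, tmax = 2.0, rmax = 2.0)   # boundary: retained
  )
  keep <- exclude_runs(m)
  expect_equal(keep[["1"]], c(1L, 4L))

  short <- dplyr::bind_rows(
    make_motion_row(1, 1, 10, tmax = 3),
    make_motion_row(1, 2, 10, tmax = 3),
    make_motion_row(1, 3, 10, tmax = 0)
  )
  expect_error(exclude_runs(short), "fewer than 2 runs")
})

test_that("percent signal change recovers hand-built window values", {
  d <- tiny_design()
  tt <- build_trial_table(d, seed = 1)
  tr1 <- tt[tt$run == 1, ]
  m <- matrix(100, nrow = 5, ncol = d$volumes_per_run)
  # raise exactly the 3 lagged instruction volumes of every trial to 102
  onv <- phase_volume_index(tr1$onset, "instruction", d)
  for (v in onv) m[, v + 3 + 0:2 + 1] <- 102
  ts <- structure(
    list(participant = 1L, run = 1L, roi = "V1", matrix = m,
         voxel_ids = 1:5),
    class = "roi_timeseries"
  )
  expect_equal(
    percent_signal_change(ts, tr1, "instruction", d)$value, 2.0
  )
  # null signal gives exactly zero
  ts0 <- ts
  ts0$matrix <- matrix(100, 5, d$volumes_per_run)
  expect_equal(percent_signal_change(ts0, tr1, "action", d)$value, 0)
  # the window starts at onset volume + lag: shifting the raised block
  # away from it must change the result
  expect_lt(
    percent_signal_change(ts, tr1, "instruction", d, lag_volumes = 4)$value, 2
  )
  ts_neg <- ts
  ts_neg$matrix[1, 1] <- -1e5
  expect_error(percent_signal_change(ts_neg, tr1, "instruction", d),
               "baseline mean")
})

test_that("selection contrast ranks responsive voxels and ignores labels", {
  d <- tiny_design()
  truth <- tiny_truth(universal_response_amplitude = 2, noise_sd = 0.5,
                      drift_amplitude = 0)
  set.seed(31)
  part <- graspmvpa:::.simulate_participant(d, truth, 1L)
  ts_list <- lapply(1:2, function(r) part$data[[r]][["V1"]])
  tbr <- lapply(1:2, function(r) part$trials[part$trials$run == r, ])
  scores <- selection_contrast(ts_list, tbr, d)
  expect_true(all(scores > 0))  # every voxel carries the universal response
  expect_gt(mean(scores), 2)

  # pure-noise voxels score near zero on average across seeds
  truth0 <- tiny_truth(universal_response_amplitude = 0, noise_sd = 1,
                       drift_amplitude = 0)
  null_scores <- unlist(lapply(1:20, function(s) {
    set.seed(s)
    part0 <- graspmvpa:::.simulate_participant(d, truth0, 1L)
    selection_contrast(
      lapply(1:2, function(r) part0$data[[r]][["V2"]]),
      lapply(1:2, function(r) part0$trials[part0$trials$run == r, ]), d
    )
  }))
  expect_lt(abs(mean(null_scores)),
            3 * stats::sd(null_scores) / sqrt(length(null_scores)))

  # relabeling orientations cannot change the score (orientation-blind)
  tbr_flip <- lapply(tbr, function(x) {
    x$orientation <- ifelse(x$orientation == "+45", "-45", "+45")
    x
  })
  expect_equal(selection_contrast(ts_list, tbr_flip, d), scores)
})

test_that("top-k voxel selection caps, keeps small ROIs, breaks ties", {
  set.seed(1)
  sel <- select_voxels(stats::rnorm(400), k = 250)
  expect_equal(length(sel$voxel_ids), 250)
  sel_small <- select_voxels(stats::rnorm(180), k = 250)
  expect_equal(length(sel_small$voxel_ids), 180)
  # tie at the boundary: lower voxel id wins, deterministically
  scores <- c(5, 3, 3, 3, 1)
  sel_tie <- select_voxels(scores, k = 2)
  expect_equal(sel_tie$voxel_ids, c(1L, 2L))
  expect_identical(select_voxels(scores, k = 2), sel_tie)
  # selected scores dominate unselected ones
  sc <- stats::rnorm(300)
  sel2 <- select_voxels(sc, k = 100)
  expect_gte(min(sel2$scores), max(sc[-sel2$voxel_ids]))
  expect_error(select_voxels(numeric(0)), "empty ROI")
})

test_that("pattern extraction reads the phase-specific windows only", {
  d <- tiny_design()
  tt <- build_trial_table(d, seed = 2)
  tr1 <- tt[tt$run == 1, ]
  n_vol <- d$volumes_per_run
  m <- matrix(0, nrow = 3, ncol = n_vol)
  onv_i <- phase_volume_index(tr1$onset, "instruction", d)
  onv_a <- phase_volume_index(tr1$onset, "action", d)
  m[, onv_i + 2 + 1] <- 7                     # instruction: onset + 4 s
  m[, onv_a + 4 + 1] <- 1                     # action: onset + 8 s
  m[, onv_a + 5 + 1] <- 3                     # action: onset + 10 s
  ts <- structure(
    list(participant = 1L, run = 1L, roi = "V1", matrix = m,
         voxel_ids = 1:3),
    class = "roi_timeseries"
  )
  sel <- select_voxels(c(3, 2, 1), k = 3, roi = "V1")
  pat_i <- extract_patterns(ts, sel, tr1, "instruction", d)
  expect_true(all(pat_i$x == 7))
  pat_a <- extract_patterns(ts, sel, tr1, "action", d)
  expect_true(all(pat_a$x == 2))  # mean of volumes at +8 s and +10 s
  expect_equal(nrow(pat_a$x), nrow(tr1))

  # invariance to values outside the extraction windows
  m2 <- m
  used <- c(onv_i + 2, onv_a + 4, onv_a + 5) + 1
  m2[, setdiff(seq_len(n_vol), used)] <- stats::rnorm(3 * (n_vol - length(used)))
  ts2 <- ts
  ts2$matrix <- m2
  expect_equal(extract_patterns(ts2, sel, tr1, "instruction", d)$x, pat_i$x)
  expect_equal(extract_patterns(ts2, sel, tr1, "action", d)$x, pat_a$x)

  expect_error(extract_patterns(ts, sel, tr1, "wait1", d), "phases")
  # last trial's action window spills past the final volume
  tr_late <- tr1
  tr_late$onset <- tr_late$onset + 16
  expect_error(extract_patterns(ts, sel, tr_late, "action", d),
               "exceeds run length")
})

test_that("detrending removes polynomial drift and keeps evoked signal", {
  d <- tiny_design()
  tt <- build_trial_table(d, seed = 6)
  # drift only: detrended series must be flat at baseline
  truth_drift <- tiny_truth(noise_sd = 0, drift_amplitude = 1,
                            universal_response_amplitude = 0)
  ts <- simulate_roi_run(d, tt[tt$run == 1, ], truth_drift, "V1", seed = 8)
  expect_gt(max(apply(ts$matrix, 1, stats::sd)), 0.1)
  flat <- detrend_run(ts)
  # each voxel becomes constant; its mean (baseline + the drift's
  # constant component) is deliberately preserved
  expect_lt(max(apply(flat$matrix, 1, stats::sd)), 1e-8)
  # evoked responses survive detrending nearly unchanged
  truth_sig <- tiny_truth(noise_sd = 0, drift_amplitude = 0,
                          universal_response_amplitude = 2)
  ts2 <- simulate_roi_run(d, tt[tt$run == 1, ], truth_sig, "V1")
  kept <- detrend_run(ts2)
  evoked <- ts2$matrix - 100
  expect_gt(
    stats::cor(as.numeric(evoked), as.numeric(kept$matrix - mean(kept$matrix))),
    0.95
  )
})

test_that("fold z-scoring uses training statistics and guards constants", {
  set.seed(4)
  train <- matrix(stats::rnorm(50), 10, 5)
  test <- matrix(stats::rnorm(25), 5, 5)
  z <- zscore_fold(train, test)
  expect_equal(colMeans(z$train), rep(0, 5))
  expect_equal(apply(z$train, 2, stats::sd), rep(1, 5))
  # test columns transformed with train statistics, not their own
  mu <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  expect_equal(z$test, (test - rep(mu, each = 5)) / rep(s, each = 5))
  # constant feature maps to zero everywhere without dividing by zero
  train[, 2] <- 3
  z2 <- zscore_fold(train, test)
  expect_true(all(z2$train[, 2] == 0) && all(z2$test[, 2] == 0))
})

test_that("voxel selection on null data leaves decoding at chance", {
  # selection is orthogonal to orientation labels: over many seeds the
  # post-selection decoding accuracy of information-free data stays at
  # chance (no selection-induced optimism)
  d <- tiny_design(list(n_runs = 4L, repetitions_per_setting = 4L))
  accs <- vapply(1:20, function(s) {
    truth <- tiny_truth(scenario = "null", seed = s, rois = "V1",
                        n_voxels = c(V1 = 60L))
    set.seed(1000 + s)
    part <- graspmvpa:::.simulate_participant(d, truth, 1L)
    runs <- 1:4
    ts_list <- lapply(runs, function(r) part$data[[r]][["V1"]])
    tbr <- lapply(runs, function(r) part$trials[part$trials$run == r, ])
    sel <- select_voxels(selection_contrast(ts_list, tbr, d), k = 30,
                         roi = "V1")
    set <- bind_patterns(lapply(runs, function(r) {
      extract_patterns(ts_list[[r]], sel, tbr[[r]], "action", d)
    }))
    loro_accuracy(filter_patterns(set, set$meta$condition == "DG"))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 2 * stats::sd(accs) / sqrt(length(accs)))
})
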