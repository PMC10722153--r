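test_that("HRF is zero at onset, peaks between 4 and 6 s, and decays", {
  tg <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_true(tg[which.max(h)] >= 4 && tg[which.max(h)] <= 6)
  expect_lt(abs(h[length(h)]), 0.005)
  expect_error(canonical_hrf(-1), "non-negative")
})

test_that("ground-truth scenarios encode the intended information layout", {
  null_t <- make_ground_truth("null", seed = 3)
  expect_equal(nrow(null_t$cells), 0)
  expect_equal(length(null_t$roi_names), 9)
  expect_equal(null_t$n_voxels_per_roi[["POIPS"]], 180L)
  expect_equal(null_t$n_voxels_per_roi[["V1"]], 300L)

  fig2 <- make_ground_truth("paper_fig2", seed = 7)
  ng_action <- fig2$cells$condition == "NG" & fig2$cells$phase == "action"
  ug_instr <- fig2$cells$condition == "UG" & fig2$cells$phase == "instruction"
  expect_equal(sum(ng_action), 0)
  expect_equal(sum(ug_instr), 0)
  expect_setequal(
    fig2$cells$roi[fig2$cells$condition == "UG" & fig2$cells$phase == "action"],
    c("V3d", "V3v")
  )
  # every pattern is unit norm
  norms <- vapply(fig2$pattern_bank, function(v) sqrt(sum(v^2)), numeric(1))
  expect_equal(unname(norms), rep(1, length(norms)))

  shared <- make_ground_truth("shared_DG_UG", seed = 1)
  cells_v2 <- shared$cells[shared$cells$roi == "V2", ]
  expect_equal(length(unique(cells_v2$pattern_id)), 1)
  cells_v1 <- shared$cells[shared$cells$roi == "V1", ]
  expect_equal(length(unique(cells_v1$pattern_id)), 2)

  anti <- make_ground_truth("antiphase", seed = 1)
  expect_equal(anti$cross_phase_sign[["V1.DG"]], -1)
  expect_equal(anti$cross_phase_sign[["V1.UG"]], 1)

  expect_error(make_ground_truth("not_a_scenario"), "unknown scenario")
})

test_that("noise-free null generator returns the constant baseline", {
  d <- tiny_design()
  truth <- tiny_truth(noise_sd = 0, drift_amplitude = 0,
                      universal_response_amplitude = 0)
  tt <- build_trial_table(d, seed = 1)
  ts <- simulate_roi_run(d, tt[tt$run == 1, ], truth, "V1", seed = 9)
  expect_equal(dim(ts$matrix), c(40, 102))
  expect_true(all(ts$matrix == truth$baseline_level))
})

test_that("simulation is deterministic given a seed and all-finite", {
  d <- tiny_design()
  truth <- tiny_truth(scenario = "paper_fig2", amplitude = 3)
  tt <- build_trial_table(d, seed = 1)
  a <- simulate_roi_run(d, tt[tt$run == 1, ], truth, "V1", seed = 11)
  b <- simulate_roi_run(d, tt[tt$run == 1, ], truth, "V1", seed = 11)
  expect_identical(a$matrix, b$matrix)
  expect_true(all(is.finite(a$matrix)))
  c <- simulate_roi_run(d, tt[tt$run == 1, ], truth, "V1", seed = 12)
  expect_false(identical(a$matrix, c$matrix))
  expect_error(simulate_roi_run(d, tt[tt$run == 1, ], truth, "V9"), "absent")
})

test_that("evoked peak matches an independent fine-grid convolution", {
  # single 1 s event, no noise: the simulated course must agree with a
  # numerically integrated boxcar*HRF at every volume
  d <- tiny_design()
  truth <- tiny_truth(noise_sd = 0, drift_amplitude = 0,
                      universal_response_amplitude = 2)
  tt <- build_trial_table(d, seed = 1)
  one <- tt[tt$run == 1, ][1, ]
  ts <- simulate_roi_run(d, one, truth, "V1")
  course <- 100 * (ts$matrix[1, ] / truth$baseline_level - 1)

  dt <- 0.005
  tg <- seq(0, 40, by = dt)
  oracle_event <- function(onset, dur) {
    h <- canonical_hrf(tg)
    resp <- stats::convolve(c(h, numeric(round(dur / dt))),
                            rev(rep(1, round(dur / dt))), type = "open") * dt
    resp <- resp / max(resp)
    function(t) {
      lag <- t - onset
      out <- numeric(length(lag))
      ok <- lag >= 0 & lag <= 40
      out[ok] <- stats::approx(seq(0, by = dt,
                                   length.out = length(resp)),
                               resp, xout = lag[ok], rule = 2)$y
      out
    }
  }
  vol_t <- (0:101) * 2
  offs <- phase_offsets_seconds(d)
  expected <- 2 * (oracle_event(one$onset + offs[["instruction"]], 1)(vol_t) +
                   oracle_event(one$onset + offs[["action"]], 4)(vol_t) +
                   oracle_event(one$onset + offs[["judgment"]], 2)(vol_t))
  # agreement up to the generator's 0.1 s convolution-grid resolution
  expect_lt(max(abs(course - expected)), 0.05)
  # peak evoked response approximates the stated amplitude; the TR grid
  # does not necessarily sample the exact continuous-time peak
  expect_equal(max(course), 2, tolerance = 0.1)
})

test_that("noise matches the requested AR(1) autocorrelation and variance", {
  d <- build_design()
  truth <- make_ground_truth(
    "null", seed = 1, rois = "V1", n_voxels = c(V1 = 200L),
    drift_amplitude = 0, universal_response_amplitude = 0,
    noise_sd = 1.5, ar1_coefficient = 0.3
  )
  tt <- build_trial_table(d, seed = 1)
  ts <- simulate_roi_run(d, tt[tt$run == 1, ], truth, "V1", seed = 21)
  resid <- ts$matrix - truth$baseline_level
  ac1 <- mean(apply(resid, 1, function(v) stats::acf(v, 1, plot = FALSE)$acf[2]))
  expect_equal(ac1, 0.3, tolerance = 0.04)
  expect_equal(stats::sd(as.numeric(resid)), 1.5, tolerance = 0.05)
})

test_that("decoding accuracy does not decrease when amplitude doubles", {
  d <- tiny_design(list(n_runs = 4L, repetitions_per_setting = 4L,
                        volumes_per_run = 102L))
  accs <- vapply(c(1, 2, 4), function(amp) {
    mean(vapply(1:4, function(s) {
      truth <- tiny_truth(
        scenario = "paper_fig2", seed = s, rois = "V1",
        n_voxels = c(V1 = 40L), amplitude = amp
      )
      set.seed(100 + s)
      part <- graspmvpa:::.simulate_participant(d, truth, 1L)
      runs <- seq_len(d$n_runs)
      ts_list <- lapply(runs, function(r) part$data[[r]][["V1"]])
      tbr <- lapply(runs, function(r) part$trials[part$trials$run == r, ])
      sel <- select_voxels(selection_contrast(ts_list, tbr, d), roi = "V1")
      set <- bind_patterns(lapply(runs, function(r) {
        extract_patterns(ts_list[[r]], sel, tbr[[r]], "action", d)
      }))
      loro_accuracy(filter_patterns(set, set$meta$condition == "DG"))$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))
})

test_that("motion traces respect thresholds and the reference frame", {
  d <- tiny_design()
  clean <- simulate_motion(d, seed = 5, participants = 1:2)
  expect_true(all(abs(clean[, c("tx", "ty", "tz")]) < 2))
  expect_true(all(abs(clean[, c("rx", "ry", "rz")]) < 2))
  first <- clean[clean$volume == 0, ]
  expect_true(all(first[, c("tx", "ty", "tz", "rx", "ry", "rz")] == 0))

  dirty <- simulate_motion(d, seed = 5, contaminated_runs = 2,
                           participants = 1)
  r2 <- dirty[dirty$run == 2, ]
  expect_true(max(abs(unlist(r2[, c("tx", "ty", "tz")]))) > 2 ||
                max(abs(unlist(r2[, c("rx", "ry", "rz")]))) > 2)
  expect_error(simulate_motion(d, seed = 1, contaminated_runs = 99),
               "n_runs")
})

test_that("datasets have the full participant x run x ROI structure", {
  d <- tiny_design()
  truth <- tiny_truth()
  ds <- simulate_dataset(d, truth, seed = 3, p_correct = 1, p_unanswered = 0)
  expect_equal(length(ds$data), 2)
  expect_equal(length(ds$data[[1]]), 2)
  expect_equal(names(ds$data[[1]][[1]]), c("V1", "V2"))
  expect_equal(nrow(ds$trials), 2 * 16)
  # deterministic responses: everything answered and correct
  acc <- behavioral_accuracy(ds$behavior)
  expect_equal(acc$accuracy, c(1, 1))
  # byte-identical regeneration from the same master seed
  ds2 <- simulate_dataset(d, truth, seed = 3, p_correct = 1, p_unanswered = 0)
  expect_identical(
    serialize(ds[c("trials", "data", "motion", "behavior")], NULL),
    serialize(ds2[c("trials", "data", "motion", "behavior")], NULL)
  )
})
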