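#' Ground truth for the synthetic BOLD generator
#'
#' Defines, per region of interest (ROI), how much decodable orientation
#' information each (condition, phase) cell carries. Orientation coding is
#' antisymmetric: +45 trials add `amplitude` times a unit-norm voxel
#' pattern, -45 trials subtract it, so a single amplitude per cell
#' controls decodability. Cells that share a `pattern_id` share decodable
#' structure (the basis of cross-condition transfer); the per-(ROI,
#' condition) `cross_phase_sign` flips the action-phase pattern relative
#' to the instruction-phase pattern, producing anti-correlated coding
#' across phases when set to -1.
#'
#' Built-in scenarios:
#' \describe{
#'   \item{`null`}{no orientation information anywhere (false-positive
#'     guard for the whole pipeline).}
#'   \item{`paper_fig2`}{information present in a condition- and
#'     area-dependent layout typical of non-visually-guided grasping
#'     studies: e.g. the early areas carry information for the instructed
#'     conditions, V3d/V3v carry it under uninformed grasping in the
#'     action phase, and the non-grasp condition carries none in the
#'     action phase. Every cell has its own independent pattern.}
#'   \item{`shared_DG_UG`}{direct-grasp and uninformed-grasp action-phase
#'     cells share one pattern in V2, V3v, VIPS and DIPS and use
#'     independent patterns elsewhere (transfer-decoding testbed).}
#'   \item{`antiphase`}{instruction- and action-phase cells share a
#'     pattern for DG/AG/NG in the early areas but the action-phase
#'     pattern is sign-flipped, so cross-phase decoding lands below
#'     chance.}
#' }
#'
#' @param scenario scenario name, or use `cells` for an explicit map.
#' @param seed integer seed for drawing the pattern bank.
#' @param amplitude orientation amplitude (percent of baseline) applied
#'   to the informative cells: a scalar, or a named vector with one
#'   value per phase. The `paper_fig2` default is phase-specific
#'   (instruction 2, action 3, judgment 3): the action-phase sampling
#'   window falls on the HRF undershoot of the same trial's instruction
#'   response, so roughly 8% of any instruction-phase pattern bleeds
#'   (sign-flipped) into the action-phase samples; instruction coding
#'   is kept at a level that is reliably decodable in its own window
#'   but whose bleed-through stays below group-level detectability.
#' @param rois ROI subset (default: all nine areas).
#' @param n_voxels named integer vector overriding per-ROI voxel counts.
#' @param baseline_level baseline signal level, arbitrary units.
#' @param universal_response_amplitude stimulus-evoked amplitude common
#'   to all conditions and both orientations, percent of baseline.
#' @param noise_sd marginal standard deviation of the AR(1) noise,
#'   signal units.
#' @param ar1_coefficient lag-1 autocorrelation of the noise.
#' @param drift_amplitude standard deviation of the per-voxel linear and
#'   quadratic drift coefficients, signal units.
#' @param cells explicit cell map: data frame with columns `roi`,
#'   `condition`, `phase`, `amplitude`, `pattern_id` (overrides
#'   `scenario`).
#' @param cross_phase_sign named numeric vector (`"ROI.condition"` ->
#'   +1/-1) overriding the scenario's sign map.
#' @return object of class `ground_truth`.
#' @export
make_ground_truth <- function(scenario = "paper_fig2", seed = 1,
                              amplitude = NULL, rois = NULL,
                              n_voxels = NULL, baseline_level = 100,
                              universal_response_amplitude = 2,
                              noise_sd = 1, ar1_coefficient = 0.3,
                              drift_amplitude = 0.5, cells = NULL,
                              cross_phase_sign = NULL) {
  all_rois <- c("V1", "V2", "V3d", "V3v", "V3A", "V7", "VIPS", "POIPS", "DIPS")
  if (is.null(rois)) rois <- all_rois
  if (!all(rois %in% all_rois)) {
    stop("unknown ROI(s): ", paste(setdiff(rois, all_rois), collapse = ", "))
  }
  nv <- stats::setNames(rep(300L, length(rois)), rois)
  if ("POIPS" %in% rois) nv[["POIPS"]] <- 180L
  if (!is.null(n_voxels)) nv[names(n_voxels)] <- as.integer(n_voxels)

  conditions <- c("DG", "AG", "NG", "UG")
  phases <- c("instruction", "action", "judgment")
  sign_map <- stats::setNames(
    rep(1, length(rois) * length(conditions)),
    as.vector(outer(rois, conditions, paste, sep = "."))
  )

  if (is.null(cells)) {
    scenarios <- c("null", "paper_fig2", "shared_DG_UG", "antiphase")
    if (!scenario %in% scenarios) {
      stop(
        "unknown scenario '", scenario, "'; available: ",
        paste(scenarios, collapse = ", ")
      )
    }
    if (is.null(amplitude)) {
      amplitude <- switch(scenario,
        null = 0,
        paper_fig2 = c(instruction = 2, action = 3, judgment = 3),
        shared_DG_UG = 5, antiphase = 5
      )
    }
    built <- .scenario_cells(scenario, rois, amplitude)
    cells <- built$cells
    sign_map[names(built$signs)] <- built$signs
  } else {
    cells <- tibble::as_tibble(cells)
    needed <- c("roi", "condition", "phase", "amplitude", "pattern_id")
    if (!all(needed %in% names(cells))) {
      stop("explicit cells need columns: ", paste(needed, collapse = ", "))
    }
    scenario <- "custom"
  }
  if (nrow(cells)) {
    stopifnot(
      all(cells$roi %in% rois), all(cells$condition %in% conditions),
      all(cells$phase %in% phases), all(cells$amplitude >= 0)
    )
  }
  if (!is.null(cross_phase_sign)) {
    stopifnot(all(names(cross_phase_sign) %in% names(sign_map)))
    sign_map[names(cross_phase_sign)] <- cross_phase_sign
  }

  set.seed(seed)
  bank <- list()
  if (nrow(cells)) {
    ids <- unique(cells[, c("roi", "pattern_id")])
    for (i in seq_len(nrow(ids))) {
      v <- stats::rnorm(nv[[ids$roi[i]]])
      bank[[ids$pattern_id[i]]] <- v / sqrt(sum(v^2))
    }
  }

  structure(
    list(
      scenario = scenario,
      roi_names = rois,
      n_voxels_per_roi = nv,
      baseline_level = baseline_level,
      universal_response_amplitude = universal_response_amplitude,
      cells = cells,
      pattern_bank = bank,
      cross_phase_sign = sign_map,
      noise_sd = noise_sd,
      ar1_coefficient = ar1_coefficient,
      drift_amplitude = drift_amplitude,
      seed = seed
    ),
    class = "ground_truth"
  )
}

# Cell layouts of the built-in scenarios. Each informative cell gets its
# own pattern id unless the scenario shares structure deliberately.
.scenario_cells <- function(scenario, rois, amplitude) {
  empty <- tibble::tibble(
    roi = character(), condition = character(), phase = character(),
    amplitude = numeric(), pattern_id = character()
  )
  signs <- numeric(0)
  if (scenario == "null") {
    return(list(cells = empty, signs = signs))
  }
  rows <- list()
  amp_for <- function(phase) {
    if (!is.null(names(amplitude))) {
      if (!phase %in% names(amplitude)) {
        stop("named amplitude vector is missing phase '", phase, "'")
      }
      amplitude[[phase]]
    } else {
      amplitude
    }
  }
  add <- function(phase, condition, roi_set, id = NULL) {
    roi_set <- intersect(roi_set, rois)
    if (!length(roi_set)) return()
    amp <- amp_for(phase)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      roi = roi_set, condition = condition, phase = phase,
      amplitude = amp,
      pattern_id = if (is.null(id)) {
        paste(roi_set, condition, phase, sep = ".")
      } else {
        paste(roi_set, id, sep = ".")
      }
    )
  }
  if (scenario == "paper_fig2") {
    early <- c("V1", "V2", "V3d")
    for (cond in c("DG", "AG", "NG")) add("instruction", cond, early)
    add("action", "DG", c("V1", "V2", "V3d", "V7", "VIPS", "POIPS", "DIPS"))
    add("action", "AG", c("V1", "V2", "V3v", "V3A"))
    add("action", "UG", c("V3d", "V3v"))
    add("judgment", "DG", c("V1", "V2", "V3d"))
    add("judgment", "AG", c("V1", "V2", "V3d", "V3A"))
    add("judgment", "UG", "V3v")
  } else if (scenario == "shared_DG_UG") {
    shared <- c("V2", "V3v", "VIPS", "DIPS")
    others <- setdiff(
      c("V1", "V2", "V3d", "V3v", "V3A", "V7", "VIPS", "POIPS", "DIPS"),
      shared
    )
    add("action", "DG", shared, id = "shared.action")
    add("action", "UG", shared, id = "shared.action")
    add("action", "DG", others)
    add("action", "UG", others)
  } else if (scenario == "antiphase") {
    early <- c("V1", "V2", "V3d", "V3v")
    for (cond in c("DG", "AG", "NG")) {
      add("instruction", cond, early, id = paste0(cond, ".shared"))
      add("action", cond, early, id = paste0(cond, ".shared"))
      flips <- stats::setNames(
        rep(-1, length(intersect(early, rois))),
        paste(intersect(early, rois), cond, sep = ".")
      )
      signs <- c(signs, flips)
    }
  }
  list(cells = dplyr::bind_rows(rows), signs = signs)
}

#' Amplitude of one ground-truth cell
#' @param truth a `ground_truth`.
#' @param roi,condition,phase cell coordinates.
#' @return the cell's amplitude (0 when the cell carries no information).
#' @export
cell_amplitude <- function(truth, roi, condition, phase) {
  hit <- truth$cells$roi == roi & truth$cells$condition == condition &
    truth$cells$phase == phase
  if (!any(hit)) 0 else truth$cells$amplitude[hit][1]
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(
    "Ground truth (scenario '", x$scenario, "'): ",
    length(x$roi_names), " ROIs, ",
    nrow(x$cells), " informative cells\n",
    sep = ""
  )
  cat(
    "  baseline", x$baseline_level, "| universal response",
    x$universal_response_amplitude, "% | noise sd", x$noise_sd,
    "| AR(1)", x$ar1_coefficient, "| drift", x$drift_amplitude, "\n"
  )
  invisible(x)
}
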