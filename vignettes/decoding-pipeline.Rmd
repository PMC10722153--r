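---
title: "ROI-based orientation decoding of grasp-related BOLD patterns: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI-based orientation decoding: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

During grasping without online visual feedback, orientation information
about the grasped object can reach visual cortex through several routes:
the visual instruction itself, proprioceptive and tactile feedback from
the hand, and feedback from action planning. Multivoxel pattern analysis
(MVPA) asks whether the distributed BOLD activity pattern of a cortical
region of interest (ROI) carries enough information to classify which of
two object orientations (+45 or -45 degrees) a trial involved, separately
for four action conditions — direct grasp (DG), air grasp (AG), non-grasp
(NG) and uninformed grasp (UG) — and separately for the instruction,
action and judgment phases of each trial.

`graspmvpa` implements that analysis end to end, together with an
event-related BOLD simulator whose ground truth is known exactly, so that
every stage — voxel selection, pattern extraction, cross-validated
decoding, group inference — can be validated against planted structure
rather than trusted on faith.

## Experimental layout

The design is fixed by the experiment being modelled: 10 participants,
one session of 10 runs, 16 trials per run, eight trial settings
(4 conditions x 2 orientations) each repeated 20 times per participant
(160 trials). A trial lasts 24 s: instruction 1 s, wait 5 s, action 4 s,
wait 8 s, judgment 2 s, inter-trial interval 4 s. Volumes are acquired
at a TR of 2 s, 198 per run.

Two layout details are not derivable from those constants and were fixed
here as package design choices:

* **Baseline placement.** 16 trials x 24 s = 384 s, but 198 volumes span
  396 s. The 12 spare seconds are baseline. They cannot all sit at the
  start of the run: the percent-signal-change (PSC) window of the last
  trial's judgment phase (onset 390 s with a 6 s hemodynamic lag) must
  still fall inside the run. The default therefore prepends 3 lead-in
  volumes and leaves 3 trailing volumes after the final trial, both used
  as baseline together with the final volume of every inter-trial
  interval (`lead_in_volumes` is configurable).
* **Trial randomization.** The randomization scheme is a free choice.
  The package deals each setting equally often into every run (two per
  run under the defaults) and shuffles order within runs. This matters:
  with an unconstrained shuffle, leave-one-run-out folds have unbalanced
  class counts, and a classifier biased toward the training majority
  class is systematically *anti*-correlated with the held-out run's
  composition. In calibration runs with unconstrained shuffles the mean
  null accuracy fell visibly below chance (~0.48); run-balanced
  randomization removes the bias (see the chance-calibration test) and
  is standard practice for event-related designs in any case. When the
  repetition count is not divisible by the run count the generator
  falls back to the unconstrained shuffle.

Volume indexing is 0-based and half-open throughout: the volume with
index `v` covers `[2v, 2v + 2)` seconds, and a phase onset maps to
`floor(onset / TR)`.

## The synthetic BOLD generator

Each ROI x run matrix (voxels x volumes) is built as

```
signal = baseline * (1 + (universal + orientation) / 100) + drift + noise
```

* **Hemodynamics.** Every task phase of every trial is a boxcar of that
  phase's duration convolved with a double-gamma HRF (peak 5 s,
  undershoot 15 s, peak:undershoot 6:1) on a 0.1 s grid. Each phase
  kernel is rescaled to unit peak, so amplitudes are expressed directly
  as peak percent signal change regardless of event duration.
* **Universal response** (default 2% of baseline) is common to all
  conditions and orientations; it is what the univariate PSC analysis
  and the stimulus-versus-baseline voxel-selection contrast see.
* **Orientation information** follows antisymmetric coding: a +45 trial
  adds `amplitude x pattern`, a -45 trial subtracts it, where `pattern`
  is a unit-norm voxel vector drawn per (ROI, condition, phase) cell
  from the seeded pattern bank. One amplitude per cell therefore
  controls decodability, zero amplitude means no information, and two
  cells are transfer-decodable exactly when they reference the same
  pattern id. A per-(ROI, condition) `cross_phase_sign` of -1 flips the
  action-phase pattern relative to the instruction-phase pattern,
  producing anti-correlated coding across phases and below-chance
  cross-phase decoding.
* **Noise** is per-voxel stationary AR(1) (default lag-1 coefficient
  0.3, marginal SD 1 signal unit = 1% of the default baseline of 100),
  plus per-voxel linear + quadratic drift with coefficient SD 0.5.
* **Voxel counts** default to 300 per ROI, with POIPS at 180 so that the
  250-voxel selection cap and the all-voxels branch are both exercised.

Built-in scenarios: `null` (no information anywhere), `paper_fig2`
(a condition- and area-dependent layout: early areas informative for the
instructed conditions, V3d/V3v informative under uninformed grasping in
the action phase, the non-grasp condition uninformative in the action
phase), `shared_DG_UG` (DG and UG share one action-phase pattern in
V2/V3v/VIPS/DIPS, independent patterns elsewhere) and `antiphase`
(instruction and action phases share patterns with a sign flip in the
early areas for DG/AG/NG).

The default `paper_fig2` amplitudes are phase-specific — instruction
2%, action 3%, judgment 3% of baseline, i.e. 2-3x the noise SD — and
were calibrated once, on exploratory seeds, so the scenario reproduces
its intended significance layout at the study's sample sizes; they are
generator constants, not fitting targets. The phase asymmetry is forced
by the trial timing: the action-phase sampling window (onset + 8/+10 s)
lies 14-16 s after the same trial's instruction onset, squarely on the
HRF *undershoot* of the instruction response, so roughly 8% of any
instruction-phase pattern bleeds, sign-flipped, into the action-phase
samples (and likewise action-phase coding bleeds into the judgment
window). This overlap is intrinsic to 24 s compound trials — real
experiments with this timing carry the same confound, and removing it
would require GLM deconvolution, which is out of scope here. At 2%
instruction coding the bleed stays below group-level detectability
while instruction-phase decoding itself remains fully powered (group
means ~0.65-0.77); at 3% the bleed in withheld-grasp cells becomes
significant (t ~ 5), which is worth remembering when interpreting weak
action-phase effects in areas with strong instruction coding.
`shared_DG_UG` and `antiphase` default to 5% ("high amplitude")
because their validation surface asserts transfer accuracies at the
0.9 level rather than mere significance.

Behavioral judgment responses are correct with probability 0.95 and
unanswered with probability 0.02 — a realistic performance level for an
easy binary judgment; unanswered trials exercise the exclusion rule in
the behavioral summary. Motion traces are bounded random walks kept
strictly inside the 2 mm / 2 degree exclusion thresholds unless a run is
deliberately contaminated with a >2 mm step.

Per-participant seeds derive from the master seed as `seed +
participant`, so any participant regenerates in isolation.

## Preprocessing

* **Detrending**: each run's voxel time series is cleaned of slow drift
  by removing its projection onto centered orthogonal polynomials
  (linear + quadratic by default; voxel means preserved). This step is
  standard fMRI practice and is load-bearing here: without it, drift
  gives every trial a shared voxel-wise offset across its phases, and a
  classifier trained on instruction-phase samples and tested on
  action-phase samples of the *same trials* (cross-phase transfer)
  exploits that offset — in calibration runs, information-free
  cross-phase accuracy rose to ~0.59 with drift present and returned to
  chance after detrending. Same-type decoding is unaffected (its train
  and test sets come from different runs).
* **Run exclusion**: a run is dropped iff maximum absolute translation
  exceeds 2 mm *or* maximum absolute rotation exceeds 2 degrees (strict
  inequalities; a participant with fewer than two retained runs is an
  error because leave-one-run-out is undefined).
* **PSC**: per voxel and event, `100 * (mean of the 3 volumes starting
  at onset volume + 3 − baseline mean) / baseline mean`, averaged over
  voxels and events; the 3-volume lag encodes the 6 s hemodynamic
  latency. The univariate lag and the MVPA windows are separate,
  independently configurable rules.
* **Voxel selection**: per participant and ROI, a Welch two-sample t
  statistic of lagged instruction-phase (stimulus) volumes versus
  baseline volumes, pooled over all conditions, both orientations and
  all retained runs; the top 250 voxels are kept (all voxels when the
  ROI is smaller). Ties at the boundary break by ascending voxel id, so
  selection is deterministic. Selection is computed once per
  participant/ROI, not per fold: pooling over orientations makes the
  score orthogonal to the decoded labels, and the null-calibration
  property test verifies that this introduces no optimism.
* **Pattern extraction**: instruction and judgment samples are the
  single volume 4 s after the phase onset (onset volume + 2);
  action samples average the volumes 8 s and 10 s after onset (onset
  volume + 4 and + 5), accommodating the 4 s movement. One sample per
  trial and phase, restricted to selected voxels, raw until fold time.
* **Z-scoring**: per cross-validation fold (or transfer direction),
  per-feature mean and SD come from the training samples only and are
  applied to both sides; zero-variance features map to 0. The scoping
  of the z-transform (run, session or fold) is not determined by the
  modelled study; fold-wise scoping was chosen because it is the only
  variant that guarantees no train/test leakage by construction.

## Decoding

The classifier is a linear soft-margin SVM (libsvm through e1071),
cost 1 by default — the field default; on well-separated synthetic data
results are insensitive to it. The design is exactly class-balanced, so
no class weighting is used. Decision values equal to zero resolve to the
first training label, keeping runs bit-reproducible.

* **Same-type**: leave-one-run-out over retained runs; each fold
  z-scores on its training runs, trains, and tests on the held-out run;
  fold accuracies average into the participant's accuracy.
* **Transfer-type**: train on all samples of condition A, test on all
  of B, and vice versa; the two directions average into one number (the
  per-direction values are retained in the result object). The default
  pair list is the six action-phase pairs.
* **Cross-phase**: the same two-direction scheme across the
  instruction/action phase pair within one condition; below-chance
  accuracy indicates anti-correlated coding.

Two numerical choices are worth stating. First, inside each fold the
z-scored feature matrix is projected onto the basis spanned by the
fold's samples (eigendecomposition of the Gram matrix). For a linear
kernel this is exact — inner products, hence the SVM solution and its
decision values, are unchanged — and it makes the many small fits cheap;
a test verifies the inner-product identity and the invariance of
predictions. Second, the SVM is fitted through libsvm's registered C
entry point directly, bypassing per-call wrapper overhead; a test
verifies that both routes return identical weight vectors.

## Group inference

Per cell (ROI x condition x phase x analysis), a two-tailed one-sample
t test across participants against the 50% chance level; PSC values are
tested against zero with the stricter default threshold p < 0.0005.
Multiple comparisons are corrected with Benjamini-Hochberg FDR at
q = 0.05. The correction family is the number of ROIs times the number
of tests of one analysis kind — for same-type decoding, all nine ROIs
crossed with every condition and phase jointly (108 tests). A
panel-wise alternative (correcting within each phase's results panel
separately) is available via `fdr_family = "panel"`; it is slightly
less conservative per panel but multiplies the families, so under a
global null the chance of *some* spurious discovery per dataset rises
roughly with the panel count. Cells in which every
participant reaches the same accuracy away from chance (saturated
signal) are reported with t = +/-Inf and p = 0 rather than erroring.

A statistical caveat is worth making explicit: BH-FDR controls the
*expected* false-discovery proportion, not the probability of any false
positive. Under a global null each correction family still produces at
least one (spurious) discovery in roughly 5% of datasets (Simes), and
when many cells carry true signal the step-up threshold rises, so a
handful of false cells among many true ones is within the procedure's
guarantees. The chance-calibration acceptance check therefore
interrogates both the per-cell coverage and the across-repetition
discovery rate, and exact set-recovery assertions are confined to the
action-phase panel.

## Validation scale

The test suite validates the pipeline at the study's own scale where the
property demands it and at reduced scale elsewhere: chance calibration
runs the full 10-participant, 9-ROI, 3-phase, 4-condition null analysis
twenty times under consecutive seeds; signal recovery, transfer
structure and antiphase checks run the full design once per scenario;
unit and property tests use 2-4 run designs with 30-60 voxel ROIs. The
acceptance script reruns the null calibration for a single ROI and
reports the mean leave-one-run-out accuracy in percent.

## What the simulator does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
event-locked hemodynamic responses, weak distributed orientation
patterns under voxel-level noise with temporal autocorrelation, slow
drift, balanced trial counts, motion-based exclusions. It deliberately
omits spatial autocorrelation between voxels, physiological (cardiac and
respiratory) noise, HRF variability across areas and participants,
task-correlated motion, and any retinotopic geometry — so passing tests
demonstrate the correctness and calibration of the *analysis*, not that
real cortical data behave this way. Real per-ROI voxel x time matrices
can be fed through the same pipeline via the plain-text dataset layout
(`read_dataset()`), provided events and motion tables accompany them.

## Known limitations

* The antisymmetric two-pattern coding model is the simplest structure a
  linear classifier can exploit; graded or nonlinear codes are out of
  scope.
* Transfer accuracy mixes the two directions into one number by
  averaging; strongly asymmetric transfer would be visible only in the
  retained per-direction values.
* The FDR family is panel-wise by default; joint-family correction
  across all panels would be slightly more conservative.
* With fewer than ~3 trials of a condition in a run, fold-wise test sets
  become small and per-fold accuracies coarse; the balanced default
  design avoids this, and unbalanced imports are handled but noisier.
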