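---
title: "Detecting awake reactivation of task patterns in resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting awake reactivation of task patterns in resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restMVPA)
```

## The analysis

After a person practises a visuomotor task, multivoxel activity patterns
resembling those evoked by the task can re-emerge in sensorimotor cortex
during subsequent awake rest. restMVPA implements the standard
pattern-analysis pipeline used to quantify this: a linear decoder is trained
to separate *task* blocks (active tracking) from *replay* blocks (passive
observation of one's own cursor movements) using spatiotemporal multivoxel
patterns from the task sessions, and the trained decoder is then slid across
resting-state runs acquired before and after training. The fraction of rest
windows labelled "task" is the reactivation statistic; its post-minus-pre
increase is compared across groups and related to behavioural improvement.

Concretely, per subject:

1. **Preprocess** each session's ROI time series: discard the first 3
   volumes (T1 equilibration), high-pass filter with a discrete-cosine
   basis (cutoff period 128 s), z-normalise each voxel within the session.
2. **Epoch** the task sessions: one spatiotemporal sample per 12 s block —
   four consecutive volumes, shifted 2 TRs (6 s) after block onset to
   account for hemodynamic delay, flattened voxel-within-volume.
3. **Decode**: linear soft-margin SVM (libsvm, fixed `C = 1`), evaluated by
   leave-one-session-out cross-validation over the first three task
   sessions, then retrained on all three for rest scoring.
4. **Score rest**: a four-volume window advances one volume at a time;
   each window is labelled task iff its decision value is strictly
   positive. A parallel nearest-template rule labels a window task iff its
   Euclidean distance to the mean task pattern is strictly smaller than to
   the mean non-task pattern. Ties go to non-task in both rules.
5. **Cohort statistics**: 2x2 mixed-design ANOVA on the task fractions
   (rest session within subjects, hand group between), post hoc paired and
   one-sample t tests with Cohen's d, Bonferroni correction with an
   explicit family size, and the Pearson correlation between the fraction
   increase and behavioural improvement (mean tracking error of sessions
   1-3 minus session 4).

## The synthetic-data generator

Because the study's fMRI data are not deposited, the package ships a
generator (`simulateCohort()` and friends) that emulates the design in ROI
space with known ground truth. Defaults follow the acquisition: TR 3 s,
four task sessions of 174 volumes with 10 task + 10 replay blocks of 12 s,
two 6 min rest runs of 122 volumes, 3 volumes discarded per run.

The forward model per session is

* **condition signal** — each condition has a fixed, unit-norm multivoxel
  pattern (replay orthogonalised against task by default); the block boxcar
  is sampled at the TR, convolved with the canonical double-gamma HRF (peak
  6 s, undershoot 16 s, ratio 6, peak scaled to 1) and multiplied onto the
  pattern with amplitude `patternAmplitude` (default 1, percent-signal
  scale);
* **noise** — independent AR(1) per voxel (coefficient 0.3, innovation SD
  1);
* **nuisance** — a cosine drift (amplitude 2, period 300 s) and a centred
  linear trend (half-range 1) shared across voxels. The trend amplitude is
  the package's choice; nothing in the emulated design pins it.

Rest runs add `n` *reactivation events*: 12 s re-insertions of the task
pattern, passed through the same HRF forward model, at uniformly drawn
non-overlapping onsets within the retained volumes. The generator records
the exact fraction of sliding windows overlapping an event. Behaviour is
linear-Gaussian: sessions 1-3 fall by a fixed learning decrement (default
5 error units/session around a 40-unit baseline, SD 3), and the session-4
error is additionally reduced by `behaviorCoupling` (default 0.3) error
units per percentage point of true reactivation increase.
`behaviorCouplingForR()` inverts the implied population correlation, which
is how the validation suite plants a known correlation of 0.6.

Block layout is not fully determined by the emulated design (174 volumes
exceed the 20 blocks' span): the package uses a 9 s initial fixation — so
the first block starts exactly where the discard window ends — 6 s gaps,
and trailing fixation, with every onset an integer multiple of the TR.

What the generator does **not** emulate: head motion, physiological noise,
spatially structured noise or voxel correlations, multi-ROI structure,
scanner reconstruction artefacts, and non-stationary rest dynamics. Tests
passing on this generator therefore validate the *pipeline's mechanics and
statistics*, not its robustness to real-scanner confounds.

## Numerical choices

* The high-pass filter regresses each voxel on a constant plus the
  `K = floor(2 * T * TR / cutoff)` leading DCT-II vectors and keeps
  residuals (`K = 5` at `T = 119`, TR 3 s, cutoff 128 s). Like any
  finite-sample projection it shows boundary leakage: a period-300 s cosine
  keeps only ~0.5% of its amplitude *at that frequency* after filtering,
  but the residual's pointwise maximum near the run edges is larger. The
  package's attenuation checks therefore measure the remaining amplitude of
  the target frequency component, not the pointwise residual.
* z-normalisation uses the sample SD (denominator T-1), per voxel, per
  session — rest runs are standardised by their own statistics. Constant
  voxels are set to zero and flagged rather than producing NaN.
* One sample per block is extracted (the block *is* one four-volume
  window); shifted windows that overrun the session are dropped, not
  truncated, so the feature length is constant.
* Both classifiers break ties (decision value exactly 0, or exactly equal
  template distances) toward non-task — conservative with respect to the
  reactivation hypothesis.
* The mixed ANOVA is the classical sums-of-squares decomposition (fitted
  via `aov()` with a subject error stratum), matching the F(1, n1+n2-2)
  reporting convention of block designs; no REML machinery is involved.
  The GLM module uses plain OLS without prewhitening — it is a sanity
  check that planted activations are where they should be, not a
  full first-level analysis.

## Validation design, and a structural insight about the fraction statistic

The validation suite simulates small cohorts (a 60-voxel ROI for the
replicate-heavy checks; 200 voxels — the generator default — for the
decodability check) and verifies, among others: exact session bookkeeping
(119 retained rest volumes, 116 windows, 20 block samples), oracle
equivalence of the filter, the template rule, and every statistical kernel,
null calibration (no planted events: task fractions near 50%, session
effects at the nominal false-positive rate), within-session event
detectability, and recovery of a planted behaviour correlation.
`scripts/acceptance.R` recomputes and prints all of these from scratch.

Two properties one might expect do **not** hold, for reasons worth
understanding before using the window fraction as an effect measure:

* **Cross-validated accuracy depends on ROI size at fixed multivariate
  SNR.** The planted patterns are unit-norm, so the class separation the
  generator produces is independent of the voxel count, but the SVM must
  estimate its weight vector from 40 samples in `4 * V` dimensions: mean
  leave-one-session-out accuracy falls as V grows (high 80s at V = 200
  versus low 90s at V = 60 under default amplitude). This is estimation
  loss, not a pipeline defect: classifying the same data with the true
  planted direction is nearly perfect.

* **The run-level task fraction is first-order blind to additive
  reactivation.** The high-pass filter removes each voxel's session mean,
  and z-scoring keeps it at zero; consequently the *mean* sliding-window
  decision value equals the decoder's bias in every rest run, planted
  events or not (the events only widen the distribution). When the null
  fraction is calibrated near 50% — which a well-behaved decoder should
  be, and which the null-calibration check separately enforces — a linear
  rule then gains from event windows almost exactly what the background
  loses from the mean shift; once event windows saturate, the net effect
  turns negative. Additive pattern injection therefore cannot raise the
  expected window fraction under per-run mean removal. The signature that
  *is* detectable, and that the suite asserts, is within-session: windows
  overlapping planted events are labelled task at a substantially higher
  rate than background windows of the same run. A real post-task increase
  in the fraction, as reported on human data, implies a *shape* change of
  the rest activity distribution rather than a superposition of extra
  task-pattern signal — a useful constraint on what "reactivation"
  must mean physiologically, and a caution against validating this
  statistic with additive simulations.

## Limitations

Single ROI per analysis; no spatial preprocessing (the generator works in
ROI space); OLS-only GLM; two-condition designs only; the window-level
fraction is reported (a volume-level variant is a trivial relabelling but
its null calibration differs, so it is not the default). Bonferroni family
sizes must be supplied explicitly by the analyst — the package does not
guess the family.
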