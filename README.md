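# restMVPA

Multivoxel decoding of task-pattern reactivation in resting-state fMRI.

After practising a motor task, activity patterns resembling those evoked by
the task can re-emerge in sensorimotor cortex during subsequent awake rest —
a candidate mechanism for offline memory consolidation. restMVPA implements
the pattern-analysis pipeline used to quantify this phenomenon, for
researchers who want to run it on ROI time series or to study its
statistical behaviour on simulated data with known ground truth.

## What it computes

A spatiotemporal decoder is trained to separate *task* blocks from *replay*
(passive observation) blocks: each block contributes one sample
`x ∈ R^(L·V)` — `L = 4` consecutive volumes × `V` ROI voxels, shifted 2 TRs
(6 s) after block onset for hemodynamic delay — after per-session
preprocessing (3 volumes discarded, DCT high-pass with a 128 s cutoff,
per-voxel z-normalisation). Two classifiers are provided:

* a linear soft-margin SVM (libsvm, fixed `C = 1`): label task iff
  `wᵀx + b > 0`;
* a nearest-template rule: label task iff
  `‖x − t_task‖₂ < ‖x − t_nontask‖₂`, where the templates are the class
  means of the training blocks.

Decoding quality is reported as leave-one-session-out accuracy over the
three training sessions. For each resting-state run, a four-volume window
slides one volume at a time and the **task fraction** — the percentage of
windows labelled task — is the reactivation statistic. Cohort inference uses
a classical 2×2 mixed-design ANOVA (rest session within subjects × hand
group between subjects, with F, p and partial eta squared), post hoc t tests
with Cohen's d, explicit-family Bonferroni correction, and the Pearson
correlation between the post-minus-pre fraction increase and behavioural
improvement (mean tracking error of sessions 1–3 minus session 4).

A synthetic-data module simulates the full multi-session design in ROI
space — HRF-convolved condition patterns, AR(1) noise, slow drift, planted
resting-state reactivation events, and behaviour coupled to the true
reactivation increase — and writes/reads datasets as 4D NIfTI + BIDS-style
events TSV + behaviour CSV.

## Worked example

```r
library(restMVPA)

cfg <- simConfig(nVoxels = 60)                     # emulated study design
run <- runPipeline(cfg, nSubjects = 6, reactEventsPost = 6, seed = 42)

run$results[run$results$method == "svm",
            c("subject", "group", "pre", "post", "diff", "losoAccuracy")]
#>  subject      group  pre post   diff losoAccuracy
#>   sub-01 right-hand 44.0 44.8  0.862         96.7
#>   sub-02  left-hand 56.0 50.0 -6.034         93.3
#>   sub-03 right-hand 41.4 41.4  0.000         98.3
#>   sub-04  left-hand 47.4 50.0  2.586        100.0
#>   sub-05 right-hand 42.2 45.7  3.448         95.0
#>   sub-06  left-hand 50.0 50.9  0.862         91.7

run$anova$svm
#>          effect df1 df2       F       p  pEta2
#> 1         group   1   4 22.7227 0.00886 0.8503
#> 2       session   1   4  0.0412 0.84899 0.0102
#> 3 group:session   1   4  0.6598 0.46221 0.1416
```

`pre`/`post` are the task fractions (%) of the two rest runs,
`losoAccuracy` the subject's cross-validated task-vs-replay accuracy (%;
chance 50). The ANOVA table tests the session effect (reactivation
increase), the group effect, and their interaction on those fractions.
`run$correlation$svm` holds the fraction-increase × behavioural-improvement
correlation. Note the small demo cohort: with six subjects the ANOVA has
error df 4, and a spurious group effect like the one above is unsurprising.

The vignette (`vignettes/reactivation-methods.Rmd`) documents the model,
every tunable parameter, the numerical choices, and two structural
properties of the statistic that anyone validating it on simulations should
know about — including why the run-level task fraction is first-order
insensitive to *additively* planted reactivation under per-run mean removal.

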