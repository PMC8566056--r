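# mselat

Lateralization of the epileptogenic hemisphere in mesial temporal lobe
epilepsy (mTLE) from resting-state fMRI, via optimized multiscale sample
entropy and SVM classification.

In drug-resistant mTLE, knowing which hemisphere harbors the seizure
focus is a prerequisite for surgery. `mselat` implements a pipeline that
lateralizes the focus from region-wise resting-state BOLD time series
(e.g. 90 cortical AAL regions × 246 timepoints per subject): it measures
each region's temporal complexity with multiscale sample entropy,
optimizes the entropy parameters against the group contrast instead of
fixing them by convention, selects biomarker regions, and classifies
subjects with a grid-searched RBF SVM under leave-one-out
cross-validation (LOOCV). Because clinical cohorts of this kind are not
shareable, the package includes a first-class synthetic generator that
plants group-dependent slow-dynamics complexity differences in known
regions, so the whole pipeline is testable end to end against ground
truth.

## The statistic

For a series *x*₁…*x*_N, coarse-graining at scale τ averages
non-overlapping windows:

y_j^(τ) = (1/τ) Σ_{i=(j−1)τ+1}^{jτ} x_i,  j = 1…⌊N/τ⌋.

Sample entropy of the coarse-grained series (Richman–Moorman estimator)
counts template matches at Chebyshev distance ≤ r·sd(x): with B the
ordered-pair match count for templates of length m and A the count for
length m+1 (both template sets over positions 1…L−m, self-matches
excluded),

MSE(τ, m, r) = −ln(A / B).

Larger values mean more irregular dynamics. The three parameters are
optimized in stages: **m** ∈ {1, 2} by the number of regions with an
intergroup t-test p < .05 across the whole (τ, r) grid; **r** ∈
0.54–0.60 by per-region ROC/AUC at the best-counting scales; **τ** ∈
1–5 by per-region AUC at the chosen (m, r). Regions with p < .01 at the
optimum are the biomarkers; their entropy values are the SVM feature
vector, with C and g = 1/(2σ²) searched over base-2 exponents −10…10.

## Worked example

```r
library(mselat)
cfg <- synthetic_config(seed = 2)   # 20 subjects, 90 regions, 9 planted
ds  <- generate_dataset(cfg)
search <- optimize_all(ds, param_grid())
mat <- entropy_matrix(ds, search$selected)
bio <- select_biomarkers(mat, alpha_final = 0.01)
cv  <- loocv(mat, bio, cfg = svm_grid_config(exponent_step = 1))
```

which prints (`print(search)`, `print(bio)`, `print(cv)`):

```
Entropy parameter search
  m stage: mean significant-region counts per m = [10.41, 8.49]; m* = 1; tau candidates by count = [3, 5]
  r stage: top-2 folded-AUC scores over r = [0.54, 0.56, 0.58, 0.60] -> [0.973, 0.970, 0.970, 0.968]; r* = 0.54
  tau stage: top-2 folded-AUC scores over tau = [1, 2, 3, 4, 5] -> [0.855, 0.810, 0.945, 1.000, 1.000]; tau* = 4
Selected: m = 1, r = 0.54, tau = 4
Biomarker set: 9 region(s) at p < 0.01 (m = 1, r = 0.54, tau = 4)
  index   region        p  auc
1    17    ROL.L 5.95e-04 0.92
2    18    ROL.R 2.98e-04 0.92
3    23 SFGmed.L 3.07e-03 0.85
4    29    INS.L 6.35e-07 1.00
...
LOOCV: 20/20 correct, mean accuracy 1.000
```

Reading the output: the m stage prefers m = 1 (more regions separate
the groups, on average, across the grid); the scale stage picks a
coarse scale (τ = 4), consistent with the planted effect living in slow
dynamics; all nine planted regions (and nothing else) survive p < .01;
and the per-subject LOOCV predictions are all correct. The `audit`
strings record each stage's scores and tie-breaks.

The same pipeline runs from a YAML config (`run_all("config.yaml")`) or
the command line (`exec/mselat` subcommands `simulate`, `entropy`,
`optimize`, `biomarkers`, `classify`, `run-all`). Real data enter as
one TSV per subject (regions × timepoints) plus a manifest of labels,
or as a preprocessed 4D NIfTI plus an integer-labelled atlas via
`extract_roi_timeseries()`.

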