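# thromboCNN

Convolutional neural network prediction of ischemic-stroke thrombus red
blood cell (RBC) content from multiparametric MRI, in R.

## The problem

Thrombus RBC content influences how well acute ischemic stroke responds to
thrombolysis and endovascular thrombectomy, but histology is only available
after retrieval. Quantitative MR maps — R2\*, quantitative susceptibility
mapping (QSM) and late-echo gradient-echo (GRE) magnitude — are sensitive
to RBCs, yet their *mean* values barely correlate with histological RBC
content at the cohort level because both R2\* and QSM are strongly
modulated by RBC oxygenation. The information survives in spatial texture,
so this package trains a small CNN regressor on 3-channel image slices
(R2\*, QSM, late-echo GRE at TE = 31 ms; 49 × 56 × 3 inputs) against the
histological RBC percentage, and evaluates it with grouped 8-fold
cross-validation (no thrombus ever contributes slices to both training and
test sides), slice-to-thrombus median aggregation, and a full
regression/classification metric suite:

* accuracy = fraction of predictions within 10 percentage points of
  histology; mean absolute error; Pearson r; regression slope;
* RBC-rich vs RBC-poor classification at the cohort-median threshold:
  accuracy, sensitivity, specificity, and the tie-corrected rank
  (Mann–Whitney) AUC with RBC-poor as the positive class;
* a naive cohort-median baseline and a [20, 45]% restricted subset
  analysis.

Training minimizes the half mean squared error, `mean((pred − y)²)/2`,
with mini-batch Adam, L2 penalty on weights and dropout. The training set
is augmented (training folds only) by the three-component scheme: RBC-bin
sampling equalization (5-point bins oversampled to `floor(cmax/c)·c`),
whole-set duplication, and one random geometric transform per duplicated
slice (rotation ±90°, integer translation ±5 px, axis reflections,
scaling 0.7–1.3, shear −30°–50°).

Because the ex vivo scans this analysis design is built around are
private, the package ships a calibrated synthetic cohort generator that
reproduces the emulated cohort's distributional statistics (median RBC 38%,
median thrombus R2\* 39 s⁻¹, median QSM 0.017 ppm, naive-baseline
accuracy ≈ 48% and MAE ≈ 10.4 points, |r(imaging, RBC)| < 0.3) while
keeping the RBC signal recoverable from texture. See the vignette
(`vignettes/thrombus-rbc-cnn.Rmd`) for the signal model and every design
decision.

## Worked example

```r
library(thromboCNN)

## 48 thrombi / 188 slices with known ground truth
coh <- generateCohort(GeneratorConfig("exvivo", seed = 1L))
cohortSummary(coh)$rbc
#>   median       q1       q3      min      max
#> 35.63187 26.28585 44.30365 16.31164 59.94007

## augmented pipeline, grouped 8-fold cross-validation
report <- runCrossValidation(
  coh,
  hp        = HyperParams(nEpochs = 14L, seed = 1L),
  augConfig = AugmentConfig(duplicationFactor = 2L, seed = 1L),
  evalConfig = EvalConfig(seed = 1L))
report
#> EvaluationReport: 48 thrombi, 8 folds
#>   thrombus-level: accuracy 85.4%  MAE 5.40  r 0.75  slope 0.66
#>   RBC-poor classification: accuracy 91.7%  AUC 0.915
```

The thrombus-level MAE of 5.4 percentage points roughly halves the naive
cohort-median baseline error (9.7 points on this cohort), and the 0.92 AUC says RBC-poor thrombi are ranked almost cleanly ahead of RBC-rich
ones — the synthetic cohort's texture signal is learnable by construction,
so these figures are an upper bound on what identical code would achieve
on real scans. `runPipeline(RunConfig(...))` drives the same computation
end to end (simulate → preprocess → cross-validate both the original and
augmented pipelines) and writes reports, prediction/ROC CSVs, the cohort
as NIfTI + manifest CSV, and a run log with every derived seed.

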