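# tairisk

Tissue-deformation metrics and injury risk curves for traumatic axonal
injury (TAI).

Rapid head rotation deforms brain tissue; when axons are stretched too far
too fast, diffuse axonal injury follows. Finite-element head models turn
measured head kinematics into per-element strain histories; the open
methodological question is how to reduce those histories to scalar injury
metrics and convert them into risk curves and thresholds that generalize
beyond the cohort they were fitted on. `tairisk` implements that chain for
researchers in injury biomechanics:

* **Constitutive layer** — Holzapfel–Gasser–Ogden (HGO) hyperelasticity for
  the brain-tissue matrix,
  `W = (G/2)(Ī₁−3) + K((J²−1)/4 − ln J / 2) + k₁/(2k₂)(exp(k₂Ẽₐ²)−1)`,
  and a tension-only dispersed-fiber energy for axonal cables with
  `Ẽₐ = κ(Ī₁−3) + (1−3κ)(Ī₄ₐ−1)`, DTI-informed dispersion
  `κ(FA) ∈ [0, 1/3]`, quasilinear viscoelastic (QLV) relaxation with a
  normalized Prony series, and least-squares calibration to shear records.
* **Tract meshing** — tractography streamlines discretized into 1-mm cable
  elements with per-element mean fractional anisotropy (FA) and eight-bin
  FA grouping.
* **Metrics** — the twelve TAI predictor candidates: 95th-percentile peak
  strain, strain rate and strain×strain-rate over brain and axonal
  elements (MPS, MPSR, MPSxSR, MAS, MASR, MASxSR) plus the six cumulative
  fraction metrics (BF-/AF-) at cutoffs, with damaged-volume-fraction
  (DVF) estimates.
* **Risk analysis** — binary logistic regression `P(x) = e^(a+bx)/(1+e^(a+bx))`,
  censored Weibull survival fits `P(x) = 1 − exp(−(x/α)^β)` (injured =
  left-censored, non-injured = right-censored), empirical ROC curves with
  AUROC, 50%-risk and optimal-ROC thresholds, and sensitivity /
  specificity / accuracy (S, SP, PAR) scoring.
* **Cross-validation** — repeated stratified 5-fold CV (50 repetitions,
  250 iterations), cutoff-grid optimization by cross-validated accuracy,
  and an end-to-end pipeline producing per-metric summary tables.
* **Validation tools** — marker-triad planar strain estimation and a
  two-sample Kolmogorov–Smirnov comparison of simulated vs experimental
  strain distributions.
* **Synthetic data** — seeded generators for cohorts, element strain
  histories, calibration records, hemisection marker fields and
  streamlines, with recorded ground truth so every downstream stage is
  testable without experimental data.

See the methods vignette (`vignettes/tai-risk-metrics.Rmd`) for the model,
its assumptions, parameter defaults and design decisions.

## Worked example

Fit and cross-validate risk curves on a synthetic 42-subject cohort
(29 injured / 13 non-injured) whose generative 50%-risk threshold is 5.0:

```r
library(tairisk)

cohort <- gen_cohort(cohort_config(), seed = 42)
fit <- fit_blr(cohort$metric_true, cohort$injured)
threshold_50(fit)
#> [1] 4.984459

cv <- run_repeated_cv(cohort$metric_true, cohort$injured, cv_config(seed = 42))
subset(cv$summary, quantity %in% c("th_blr", "th_weibull", "th_roc", "PAR_roc"))
#>   quantity      mean         sd
#> 2   th_roc 5.0098925 0.09447565
#> 3  PAR_roc 0.9898889 0.04894537
#> 7   th_blr 5.0101846 0.09369992
#> 12 th_weibull 5.0587737 0.15574530
```

All three analyses recover the planted threshold to within ~1% on held-out
folds, with the cross-validated accuracy (PAR) near 0.99 — this steep-link
default cohort is close to separable, which is exactly the regime where
the separation-capped logistic fit matters.

The full pipeline — histories for 2,000 brain and 1,000 axonal elements
per subject, cutoff sweeps for the six fraction metrics, then 250 CV
iterations for all 12 metrics:

```r
res <- run_full_pipeline(cohort_config(), seed = 42)
unlist(res$cutoffs)
#>    MPS   MPSR MPSxSR    MAS   MASR MASxSR
#>   0.24 144.00  23.60   0.10  50.00   3.40
head(res$cv_tables$roc[c("metric", "PAR_roc_mean", "auroc_mean", "th_roc_mean")], 3)
#>   metric PAR_roc_mean auroc_mean th_roc_mean
#> 1    MPS        1.000      1.000       0.163
#> 2   MPSR        0.901      0.987     100.494
#> 3 MPSxSR        0.973      1.000      10.141
res$dvf_group_means
#>   injured   AIV DVF_MPS DVF_MPSR DVF_MPSxSR DVF_MAS DVF_MASR DVF_MASxSR
#> 1       0 0.034   0.016    0.038      0.012    0.24      0.9       0.32
#> 2       1 0.528   3.385    4.076      2.630    3.56      7.9       4.52
```

The table mirrors the structure of a metric-comparison study: mean ± SD of
accuracy, sensitivity, specificity, fit quality and thresholds per metric
over 250 iterations (`res$cv_tables$blr`, `$roc`, `$weibull`), plus the
DVF-vs-AIV comparison showing damaged-volume estimates higher in the
injured group for every metric.

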