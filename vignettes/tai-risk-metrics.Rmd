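---
title: "Deformation metrics and risk curves for traumatic axonal injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation metrics and risk curves for traumatic axonal injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tairisk)
```

## The problem

Traumatic axonal injury (TAI) arises when rapid head rotation deforms brain
tissue fast enough to stretch axons past their tolerance. Finite-element
head models translate measured head kinematics into tissue strain fields;
injury criteria then reduce those fields to scalar metrics and calibrate
risk curves against observed injury outcomes. `tairisk` implements that
computational chain as a reusable, testable pipeline: the constitutive
model of white matter as a fiber-reinforced hyper-viscoelastic composite,
the reduction of per-element strain histories to twelve injury metrics, and
the statistical machinery (logistic, censored-Weibull and ROC risk
analyses under repeated stratified cross-validation) that turns per-subject
metrics and binary injury labels into thresholds with honest
generalization estimates.

Because the animal cohort and imaging data such a study rests on are not
publicly available, the package ships a synthetic-data module that emulates
every input with known ground truth — which is also what makes the whole
chain testable end to end.

## Tissue model

White matter is decomposed into a mostly isotropic matrix and embedded
axonal fiber bundles. The matrix strain energy is the isotropic form of the
Holzapfel–Gasser–Ogden (HGO) family,

$$W = \frac{G}{2}(\bar I_1 - 3)
  + K\left(\frac{J^2 - 1}{4} - \frac{\ln J}{2}\right)
  + \frac{k_1}{2 k_2}\left(e^{k_2 \tilde E_a^2} - 1\right),
  \qquad \tilde E_a = \tfrac{1}{3}(\bar I_1 - 3),$$

with shear modulus $G$, bulk modulus $K$ and fiber-like parameters
$k_1, k_2$. The $\tfrac13$ in $\tilde E_a$ is the isotropic limit of the
HGO dispersion parameter (`KAPPA_ISO`): with $\kappa = 1/3$ the anisotropic
fiber strain degenerates exactly to this form, which is how the package
interprets the dispersion constant appearing in the isotropic matrix
energy. Axonal fibers carry the anisotropic term only,

$$W_f = \frac{k_1}{2 k_2}\left(e^{k_2 \tilde E_a^2} - 1\right),
  \qquad \tilde E_a = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_{4a} - 1),$$

where $\kappa \in [0, 1/3]$ encodes fiber dispersion and is mapped from the
DTI fractional anisotropy of each element via `kappa_from_fa()`
($\kappa(FA{=}1) = 0$ aligned, $\kappa(FA{=}0) = 1/3$ isotropic). Both
shipped parameter sets use $k_2 \to 0$; below $k_2 = 10^{-8}$ the code
switches to the analytic limit $(k_1/2)\tilde E_a^2$ to avoid a $0/0$.
Continuity across the switch is tested to $10^{-8}$ relative.

Three modelling conventions deserve note:

* **Cable kinematics.** Axonal elements are one-dimensional, so there is no
  volumetric split; $\bar I_{4a} \equiv \lambda^2$ with $\lambda$ the axial
  stretch. When a host-element $\bar I_1$ is not supplied, the isochoric
  uniaxial value $\lambda^2 + 2/\lambda$ is used (irrelevant at
  $\kappa = 0$, the aligned default).
* **Tension only.** Fibers store no energy and carry no stress for
  $\lambda \le 1$; buckled axons do not push.
* **QLV.** The deviatoric stress relaxes through a quasilinear viscoelastic
  hereditary integral against a normalized single-term Prony series.
  `qlv_convolve()` uses a recursive internal-variable update that is exact
  for piecewise-linear elastic stress; the direct $O(n^2)$ convolution
  survives only as a test oracle. Prony coefficients that do not sum to one
  (as when relaxation moduli are quoted in stress units) are renormalized
  with a warning.

Default parameters (`default_matrix_params()`, `default_fiber_params()`):
$G = 3.0478$ kPa, $K = 2.19$ GPa, matrix $k_1 = 35.767$ kPa, fiber
$k_1 = 43.432$ kPa, $k_2 \to 0$, $g_1 = 0.8909$, $g_\infty = 0.109$
(normalized), $\tau = 0.035$ s, $\rho = 1.04$ g/cm³. Calibration
(`calibrate_matrix()`) is bounded nonlinear least squares on shear records;
any bounded optimizer is acceptable for this problem, and acceptance is on
SSE decrease and parameter recovery, not optimizer identity. The
embedded-element stiffness correction is kept as bookkeeping
(`stiffness_ratio_spec()`: $R = G_f/G_m - 1$, $R_v = R/\gamma_V$) because
no closed-form mapping from $R_v$ to the fiber $k_1$ is available; the
shipped fiber value is therefore a fixture, and the scaling is left
configurable.

## From streamlines to elements

`discretize_streamlines()` cuts each tractography polyline into
`round(arclength / 1 mm)` equal-length cable elements (minimum one),
preserving total arclength; streamlines shorter than half an element are
skipped and counted. Each element receives the arithmetic mean of the FA
samples on its span (endpoint-inclusive; a span with no sample falls back
to the nearest one). `group_by_fa()` bins elements into eight FA decades
$[0.2, 0.3), \dots, [0.9, 1]$ — half-open with a closed top bin, since
range labels do not specify edge ownership — and elements below the 0.2
tractography stopping threshold are retained but flagged rather than
deleted: the 0.2 cutoff is a tracking criterion, not a meshing rule.

## The twelve metrics

From each subject's element strain histories (brain solids carry the first
principal strain, axonal cables the axial logarithmic strain, both sampled
at 0.1 ms):

* **Magnitude metrics** — MPS, MPSR, MPSxSR (brain) and MAS, MASR, MASxSR
  (axonal): the 95th percentile over elements of the per-element peak
  strain, peak strain rate, and peak strain-times-strain-rate. The 95th
  (not 100th) percentile suppresses isolated numerical artifacts;
  `percentile95()` uses the linear-interpolation sample quantile,
  unweighted over elements.
* **Fraction metrics** — BF-MPS/BF-MPSR/BF-MPSxSR and
  AF-MAS/AF-MASR/AF-MASxSR: the fraction of elements whose peak strictly
  exceeds a cutoff, volume-weighted for brain elements and count-weighted
  for the uniform 1-mm axonal elements (for which count and length
  weighting coincide).

Rates are forward differences of the 5-point moving-average-smoothed
strain; smoothing applies to both brain and axonal rate metrics. At the
series edges the window is truncated to the available samples (the first
point of a 5-window series averages indices 1–3). The strain-times-rate
series is the signed product of the smoothed strain at the start of each
interval with that interval's rate; with monotone loading its maximum
falls in the loading phase, and the signed (not absolute) product is the
documented, switch-free convention. Damaged-volume-fraction estimates
multiply axonal fractions by the fiber volume fraction
$\gamma_V = 0.5$; brain fractions already are volume fractions.

Default cutoffs are MPS 0.30, MPSR 120 s⁻¹, MPSxSR 28 s⁻¹, MAS 0.13,
MASR 70 s⁻¹, MASxSR 7.5 s⁻¹, and the sweep grids span MPS 0.14–0.34,
MPSR 60–200 s⁻¹, MPSxSR 4–32 s⁻¹, MAS 0.10–0.22, MASR 10–90 s⁻¹,
MASxSR 1–9 s⁻¹ at 11 points each (the grid resolution is a package
choice; no canonical step size exists).

## Risk curves and cross-validation

`fit_blr()` fits $P(x) = e^{a+bx}/(1+e^{a+bx})$ by maximum likelihood
(through `stats::glm`; an independent Newton–Raphson oracle checks the
coefficients in the tests). Fit quality is a sum-of-squares $R^2$ on the
0/1 outcomes adjusted by $(n-1)/(n-2)$ — one of several "adjusted $R^2$"
variants in circulation; this package supports exactly this one and says
so. Perfectly separable training folds are a real possibility at $n = 42$,
so separation is flagged and the slope capped at $50/\text{range}(x)$ with
the 50% threshold preserved, rather than allowed to diverge.

`fit_weibull()` fits $P(x) = 1 - e^{-(x/\alpha)^\beta}$ under the standard
injury-risk-curve censoring convention: an injured subject's (unobserved)
tolerance is left-censored at its metric value, a non-injured subject's is
right-censored. The likelihood is maximized directly over
$(\log\alpha, \log\beta)$; `survival::survreg` with interval2 coding is
the independent cross-check in the tests, never the implementation. A
fraction metric can be exactly zero for an injured subject, which has zero
likelihood under any Weibull; such values are floored at half the smallest
positive metric value. Note that a binary censored cohort carries little
information about the shape parameter — at $n = 2000$ the MLE of $\beta$
has a sampling SD of roughly 3% — so recovery checks average the MLE over
replicate cohorts rather than pretending one cohort pins $\beta$ down.

`roc_curve()` builds the empirical ROC over midpoint thresholds
(classification is strict `>`; ties count negative); the trapezoidal AUROC
equals pairwise concordance with ties at ½, verified exactly against a
brute-force count. `optimal_roc_threshold()` takes the point closest to
the (0, 1) corner, weighting sensitivity and specificity equally, with
ties broken by higher sensitivity then lower threshold, and the returned
threshold placed at the midpoint between adjacent distinct metric values.

`run_repeated_cv()` wraps all of this in stratified 5-fold cross-validation
repeated 50 times (250 iterations by default): thresholds are always
estimated on the training folds and applied unchanged to the held-out
fold; data are reshuffled, re-stratified and re-partitioned before each
repetition; one master seed spawns per-repetition seeds. Fold assignment
balances sizes within each class *and* overall to within one subject. With
42 subjects the realized training fractions are 78.6–81.0% — the
implementation reports the actual per-iteration split sizes rather than a
nominal percentage. Training folds with a single class (impossible under
default stratification, possible with user data) are skipped and counted,
not imputed. `optimize_cutoff()` sweeps a cutoff grid, scoring each cutoff
by cross-validated mean accuracy (PAR) with AUROC as first tie-break; the
remaining tie-break prefers the *larger* cutoff, which predicts the
smaller damaged volume.

## Synthetic data: what it emulates, and what it does not

`gen_cohort()` draws 42 subjects (29 injured / 13 non-injured by default)
with peak angular velocities in 89.54–203.14 rad/s and peak accelerations
in 18.43–72.36 krad/s². Velocity severity maps linearly onto a latent
MASxSR-like metric in 2.5–11.5 s⁻¹, and the axonal injury volume follows
$\mathrm{AIV} = A_0 \, g(x) \, e^{\varepsilon}$ with $g$ logistic
(slope 3 per metric unit, 50% point $\theta^* = 5$), $A_0 = 0.52$ and
log-normal noise (sd 0.3) so that AIV is always positive and the 0.26%
label threshold sits exactly at the 50%-risk point. The expected injured
fraction is then ≈ 0.71 ≈ 29/42; exact-count mode redraws with spawned
sub-seeds (bounded retries) until the 29/13 targets are met. The peak
acceleration draw is partially coupled to velocity (weight 0.7) because
faster actuator pulses are also sharper; this is what lets strain-rate
metrics co-vary with severity, as they must for rate-based risk curves to
be meaningful.

`gen_kinematics()` uses a haversine pulse
$\omega(t) = \omega_p \sin^2(\pi t / T)$ with $T = \pi\omega_p/\alpha_p$ —
the measured actuator traces it stands in for are unavailable, and this
shape hits both peak velocity and peak acceleration exactly.
`gen_element_histories()` gives every element a haversine strain pulse
whose duration is half the kinematic pulse (tissue strain transients are
briefer than the loading pulse) with log-normal per-element peaks whose
median scales with severity, so doubling severity exactly doubles the
median peak. Axonal peaks are brain peaks times a Beta(4, 6) attenuation
(mean 0.4), reflecting the observation that tract-oriented strains are
markedly — on the order of 75% — smaller than principal strains. Under the
defaults the cohort's per-subject 95th-percentile MPS lands inside
0.10–0.50 and peak strain rates reach the tens-to-hundreds s⁻¹.

What the generator does **not** emulate: spatial anatomy and regional
injury localization, brain–skull boundary mechanics, and any correlation
structure between neighboring elements. Passing tests therefore
demonstrate that the *pipeline* recovers planted generative truths
(thresholds, cutoffs, attenuation ordering) — not that the defaults
reproduce any particular animal's strain field.

## Hemisection validation

`triad_deformation()` reconstructs the planar deformation gradient of an
ink-marker triad as the unique linear map on the two triangle edge
vectors — exact for affine motions, which is also the natural resolution
limit of a three-point estimate. The strain measure for distribution
comparison defaults to the principal Green strain, with principal
logarithmic strain available, since the original marker-processing choice
is not documented. `ks_two_sample()` computes the exact two-sample
supremum statistic and an asymptotic p-value with the standard
small-sample effective-$n$ correction
$\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})D$; exact enumeration is
not attempted. `compare_sim_experiment()` packages the two cumulative
curves, $D$, $p$ and a pass/fail at $p > 0.05$ (curves *not* statistically
different). The original triad-to-element matching with interpolation over
up to four surrounding elements is replaced by the deterministic
nearest/inverse-distance rule on the synthetic marker fields.

## Numerical choices and problem sizes

* Output step fixed at 0.1 ms; QLV and rate computations assume a uniform
  grid and refuse non-uniform ones.
* `calibrate_matrix()` uses L-BFGS-B with wide positive bounds; if the
  optimizer ever returns a worse SSE than the start, the start is
  returned (the SSE never increases).
* Degenerate inputs fail loudly: singular deformation gradients, collinear
  triads, single-class label vectors, all-zero weights and empty samples
  are errors, not NaNs.
* Default end-to-end sizes — 42 subjects, 2,000 brain + 1,000 axonal
  elements, 12 metrics, 250 CV iterations, 11-point cutoff grids with a
  lighter ROC-only CV inside the sweep — run in well under a minute on one
  CPU. The test suite uses reduced element counts (200–400) and fewer
  repetitions where full sizes add nothing to the property under test, and
  averages threshold recovery over 200 seeded cohorts.

## Known limitations

* The constitutive module is a material-point implementation: no FE
  assembly, contact, or brain–skull connectors; it exists to define,
  calibrate and verify the material laws the pipeline's strain inputs
  presuppose.
* The mapping from the effective stiffness ratio $R_v$ to fiber stiffness
  parameters is not specified by the source methodology; the package ships
  the fiber parameters as a fixture and leaves the scaling to the user.
* Green-to-logarithmic strain conversion is exact
  ($e = \ln\sqrt{1+2E}$), but published two-decimal conversions of 0.21
  round to 0.18/0.17 depending on convention; the package reports full
  precision and leaves rounding to the caller.
* The Weibull shape parameter is weakly identified by binary censored
  cohorts of realistic size; treat fitted $\beta$ (and hence the shape of
  the low-dose tail) with corresponding caution.
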