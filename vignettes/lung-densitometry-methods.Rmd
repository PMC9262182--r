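---
title: "Quantitative CT lung densitometry for air-trapping diagnosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT lung densitometry for air-trapping diagnosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungdens)
```

## The clinical problem

Bronchiolitis obliterans (BO) is a chronic obstructive disease of the small
airways, seen in children after haematopoietic stem-cell transplantation or
severe respiratory infection. Its radiological hallmark is *expiratory air
trapping*: regions of lung that fail to densify when the child breathes
out, producing a mosaic of abnormally lucent parenchyma on expiratory CT.
Young children often cannot perform reliable spirometry, so a quantitative
marker computable from a paired inspiratory/expiratory CT — which children
as young as four or five can cooperate with — is clinically valuable.

`lungdens` implements the full analysis chain for this problem: the
lung-density index (LDI) panel from paired-phase Hounsfield-unit (HU)
volumes, the diagnostic evaluation of those indices (group comparison,
adjusted regression, ROC cutoff analysis), and a synthetic phantom and
cohort generator so the chain can be exercised and validated end to end
without patient data.

## The lung-density index panel

Given a phase's HU volume and an aligned lung mask, the package computes,
per side and for the whole lung (whole-lung values are voxel-weighted over
the union of the two lungs, never an average of per-side indices; per-side
values are always reported alongside):

* **Lung volume** (mL): voxel count × voxel volume.
* **MLD** (HU): unweighted arithmetic mean of masked HU values.
* **MLDD** (HU): expiratory MLD − inspiratory MLD. The sign convention is
  fixed so that healthy lungs, which densify on expiration, give positive
  MLDD; a small MLDD means air trapping. (With typical values, e.g.
  −659 − (−788) = 129 HU in health.)
* **E/I volume, E/I MLD** (%): `100 · expiratory / inspiratory`, computed
  on signed HU for MLD. Because both MLDs are negative, a lung that fails
  to densify has E/I MLD close to 100%.
* **LAA fractions E850/E900/E950** (%): percentage of *expiratory* masked
  voxels with HU strictly below −850/−900/−950 (low-attenuation, trapped
  lung).
* **HAA fractions E600/E650** (%): percentage of expiratory masked voxels
  with HU strictly above −600/−650 (normally densified lung).

Voxels exactly at a threshold count for neither tail — a symmetric,
testable convention (the partition *below t / in [t1, t2] / above t2* sums
to exactly 100%). HU values outside the CT plausibility window
[−1024, 3071] are reported with a count but never clipped, since synthetic
Gaussian noise legitimately produces a handful of such voxels.

A deliberately simple threshold segmenter (`simple_lung_segment()`:
air-threshold, border-connected background removal, two largest 6-connected
components, left/right by centroid) is provided as a convenience for
phantoms; it is not a clinical segmentation method, and all indices accept
externally produced masks.

## The phantom generator

`phantom_spec()`/`generate_phantom()` build a paired-phase thorax with
known ground truth:

* Two ellipsoidal lungs inside soft tissue (default +40 HU). Inspiratory
  parenchymal density is `N(mu, sigma^2)` with an age trend on the mean of
  −15 HU per year around a 12-year reference (the reported paediatric
  age–MLD slope); default `mu` −788 HU, `sigma` 60 HU, plus independent
  per-phase sensor noise (default SD 10 HU).
* Expiration shrinks each ellipsoid to `expiratory_volume_ratio` times its
  inspiratory volume (default 0.58, a healthy child's value). The
  expiratory lattice is a subset of the inspiratory one, and matched voxels
  share the same underlying density draw.
* A fraction `trapped_fraction` of expiratory parenchymal voxels keeps its
  inspiratory density; the rest shifts by `delta_exp` (default +130 HU).
  Trapped voxels are clustered around blob seeds drawn in
  ellipsoid-normalised coordinates (mosaic attenuation, not
  salt-and-pepper); clustering changes the spatial pattern but not the
  closed-form expectations, because membership is still an exact fraction
  of voxels. No voxel-to-voxel registration between phases is modelled —
  none of the indices requires it.

Every index then has a closed form (`analytic_expectations()`): the
expiratory density is a two-component Gaussian mixture, so
`E[EXP MLD] = mu + (1 − p)·delta`, `E[MLDD] = (1 − p)·delta`, and each
threshold fraction is a mixture of Gaussian CDFs with total SD
`sqrt(sigma^2 + noise^2)`. These expectations were verified against an
independent 10^6-draw Monte-Carlo simulation of the mixture before being
frozen into the test suite. Lattice discretisation affects only the volume
ratio; the documented bound (`ei_volume_discretization_bound()`) is the
one-voxel surface-shell worst case, and the recovery tests require the
observed E/I volume to fall within it.

All randomness flows from one top-level seed through named substreams
(geometry, density, noise, cohort), so a change in one draw cannot perturb
another and identical seeds give bit-identical volumes.

## The cohort simulator

`generate_cohort_table()` draws subject records at two group sizes
(default 30 controls / 51 BO, the study design this package reproduces)
with marginal means and SDs taken from the published group summaries for
every PFT and LDI variable (`cohort_variable_defaults()`). Dependence is
introduced by a Gaussian copula: latent multivariate normal with unit
diagonal and configurable pairwise correlations, scaled by each group's
mean/SD. The default pairs — MLDD–FEV1 0.5, E/I MLD–FEV1 −0.5, E900–sRaw
0.6, E850–sRaw 0.6, E900–E850 0.5 — echo the strongest published
index–PFT associations but are *assumptions*: the source tables report
regression coefficients, not a correlation matrix, so the copula defaults
are an implementer's choice, and the latent `r` maps to Spearman's rho as
`(6/π)·asin(r/2)`. The control SD of E950 is exactly zero in the published
table, so E950 is excluded from the default pairs (its rank correlation is
undefined in controls).

Percent-scale variables are *truncated* at their bounds (E-fractions and
E/I ratios to [0, 100], percent-predicted PFTs at 0), not resampled;
at the default parameters the worst case is E/I MLD in the BO group
(~9% of draws clamp at 100), which biases that group mean down by well
under one SD — negligible for every test the package runs. Ages are drawn
from normals matched to each group's median and IQR and
rejection-truncated to the study's 3–18-year window; sex is Bernoulli with
each group's male fraction; measurement-set missingness (spirometry,
plethysmography/diffusion) is applied jointly per subject at the published
completion rates.

What the simulator does *not* emulate: within-subject arithmetic
consistency (a simulated subject's MLDD is drawn, not computed from its
drawn MLDs), skewed or heavy-tailed marginals (sRaw in BO is strongly
right-skewed in reality), and any age–severity dependence within group.
Passing tests therefore validate the analysis machinery and its
statistical behaviour under a Gaussian-copula design, not distributional
realism of any single clinical variable.

## Diagnostic statistics

* **Group comparison**: two-sided Mann-Whitney for continuous variables
  (exact when feasible; normal approximation with continuity correction
  under ties), chi-square with Yates correction for 2×2 tables. Analyses
  are complete-case per variable and always report the per-group n.
* **Adjusted regressions**: OLS with age and sex always included;
  univariate (one PFT at a time), backward elimination (drop the largest-p
  predictor until all retained p < 0.05; covariates never dropped), or
  all-subset selection by AIC. Logistic regression reports the OR per unit
  with a 95% Wald interval; (quasi-)complete separation — a diverging
  slope under a 0/1 fitted-probability warning or failed IRLS — is raised
  as an explicit error, as is non-convergence. Note the backward type-I
  property: the last survivor of max-p elimination is the *minimum*-p
  predictor, so with k pure-noise predictors the retain-nothing rate is
  about `(1 − 0.05)^k`, not 95%.
* **ROC analysis**: AUC by the rank (pair-counting) estimator with ties
  0.5 — proven equal to the trapezoidal area under the empirical ROC curve
  on every fixture. Orientation is auto-selected so AUC ≥ 0.5 and recorded.
  The 95% CI uses the DeLong placement-variance method (cross-checked
  against pROC in the tests) or a seeded stratified bootstrap. The cutoff
  maximises sensitivity + specificity over observed values with the rule
  "predict BO when the oriented score passes the cutoff inclusively"; ties
  are broken toward higher specificity, then toward the more extreme
  cutoff — both deterministic. Confusion counts and sens/spec/PPV/NPV
  accompany every cutoff; metrics with a zero margin are flagged
  undefined, never reported as numbers.

Alpha is 0.05 two-sided throughout with no multiplicity correction,
matching the analysis design this package reproduces.

## Numerical and design choices

* Strict inequalities at HU thresholds (the convention is otherwise
  unstated in the field's descriptions); equal-valued voxels belong to no
  tail.
* MLDD is always expiratory − inspiratory; E/I MLD is computed on signed
  HU. Both conventions are forced by the arithmetic of the published
  control-group values (129 HU; ≈83.9%).
* Phantom volumes are written as float64 NIfTI by default so that the
  write/read round trip is lossless; int16 (integer HU, as clinical CT
  stores it) is available and documented as rounding.
* Group-mean arithmetic caveat: averaging per-subject ratios does not
  equal the ratio of group means, and differencing rounded group means
  need not equal the mean of per-subject differences; the package always
  computes per-subject first.
* Problem sizes in the shipped tests and scripts: phantoms of 96×96×72
  voxels (~10^5 parenchymal voxels, enough for 3-SE Monte-Carlo recovery
  checks of the closed forms), 200-replicate power checks of the cohort
  simulator at n = 30/51, and 100-replicate planted-coefficient recovery
  at n = 500–1000. These sizes make every Monte-Carlo tolerance explicit
  and keep a full run in tens of seconds on a laptop.

## Known limitations

* Masks are an input; the bundled segmenter is a phantom-grade
  convenience.
* HU calibration, scanner kernels, dose, iterative reconstruction and
  deformable registration between phases are out of scope; inputs are
  assumed calibrated.
* The cohort simulator's Gaussian-copula design cannot reproduce
  real-data AUCs or cutoffs — its large-sample MLDD AUC converges to the
  binormal value `Φ(Δ/√(σ₁² + σ₂²)) ≈ 0.82` at the default calibration,
  which is a property of the generator, intentionally not asserted equal
  to any real cohort's value.
* Density mapping / parametric response mapping and percentile-density
  indices are different methods and are not implemented.
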