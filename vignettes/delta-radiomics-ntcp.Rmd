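---
title: "Delta-radiomics NTCP modelling of late xerostomia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics NTCP modelling of late xerostomia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiotherapy of head-and-neck cancer frequently damages the parotid glands
and leaves patients with chronic dry mouth (xerostomia). Normal tissue
complication probability (NTCP) models predict this risk before treatment
from the planned mean gland dose and baseline complaints, but they ignore how
an individual patient's glands actually respond once treatment starts. Weekly
in-treatment CT shows the parotids shrinking at patient-specific rates, and
the shape of that early response carries prognostic information: glands that
lose surface area quickly by treatment week 3 flag patients at elevated risk
of permanent damage, while treatment can still be adapted.

`xerodelta` implements the full analysis pipeline for this question:
longitudinal radiomics feature extraction from CT volumes and gland masks,
weekly *delta-features* (in-treatment change relative to a baseline scan),
bootstrapped variable selection, multivariable logistic NTCP models, and
bootstrap internal validation with optimism-corrected coefficients. Because
no patient-level dataset is distributed with the package, a synthetic-cohort
generator with a fully known ground truth is a first-class module: every
downstream stage is exercised and tested against data whose generating
mechanism is known exactly.

## The model

The endpoint is binary moderate-to-severe patient-rated xerostomia 12 months
after radiotherapy (`xer_12m`; a 6-month endpoint is available as a secondary
option). The headline NTCP model is a logistic regression on the raw clinical
scales

$$
\mathrm{logit}\, P(\mathrm{Xer}_{12m} = 1) =
  \beta_0 + \beta_1\,\mathrm{Xer}_{baseline} + \beta_2\,\mathrm{dose\ [Gy]} +
  \beta_3\,\Delta\mathrm{PG\text{-}surface}_{w3}\ [\mathrm{cm}^2],
$$

where $\Delta$PG-surface$_{w3}$ is the change in contralateral parotid mesh
surface area between the planning CT and the week-3 CT. Shrinkage makes this
delta negative, so a negative $\beta_3$ (odds ratio below 1 per cm²) means
*larger reduction, higher risk*. The pre-treatment reference model drops the
delta term; "delta-feature model 1" replaces dose with the delta term.

### Delta-features and their asymmetric baselines

Geometric features change meaningfully from the planning scan onward, so
geometric deltas use the planning CT (week 0) as baseline. Intensity and
texture features are confounded by the intravenous contrast agent given only
at planning, so their deltas use the week-1 CT (acquired without contrast,
before meaningful anatomical change) as baseline. Deltas therefore exist for
weeks 2–6, and the planning scan never enters an intensity/texture delta.
This asymmetry is enforced structurally by `delta_features()`, not left as a
convention. The sign convention is *later minus baseline* throughout: the
literal reading "subtract weekly from planning" would flip every sign and
contradict both the negative published surface coefficients (OR < 1) and the
use of a negative median reduction, so the package documents and uses
later-minus-baseline.

Axial slices flagged for metal artefacts are removed before intensity/texture
extraction (`exclude_artifact_slices()`); geometric features always use the
complete delineation.

### Feature catalogue

`extract_features()` returns 15 geometric, 17 first-order intensity, and 33
texture features (GLCM, GLRLM, GLSZM, NGTDM families), defined in the
standard IBSI style. The published analysis used supplementary lists of
15/17/66 features whose exact composition is not in the main text; the
catalogue here is a representative IBSI-aligned set that contains every
feature the main analyses name: surface, volume, bounding-box volume,
volume x mean intensity, compactness, median, kurtosis, NGTDM coarseness and
GLSZM large-zone low-grey-level emphasis. Conventions for degenerate ROIs are
fixed so that every feature is finite for every non-empty ROI: GLCM
correlation of a zero-variance ROI is 0, NGTDM coarseness is capped at
$1/\epsilon = 10^6$ ($\epsilon = 10^{-6}$), and kurtosis is reported in the
Pearson (non-excess) convention, i.e. a normal distribution scores 3.

Texture matrices are built on the anisotropic voxel lattice without
resampling (distance-1 neighbours are lattice neighbours; 13 unique 3D
directions for GLCM/GLRLM, 26-connectivity for GLSZM zones and NGTDM
neighbourhoods). Intensities are discretized with a fixed bin width, default
25 HU, anchored at the ROI minimum — so a global HU shift leaves all texture
features unchanged, which is exactly why contrast enhancement forces the
week-1 baseline for this family.

### Mesh surface area

Surface area is the pipeline's most important geometric quantity. An
iso-surface of the *binary* mask systematically overestimates the area of
smooth bodies — the staircase artefact contributes about +7% on a
voxelized sphere of radius 12 voxels, far outside the 2% accuracy the
surface-change analysis deserves. The package therefore computes the signed
Euclidean distance field of the mask (exact, spacing-aware), smooths it
gently (Gaussian, $\sigma$ = 0.7 voxels), and measures the triangulated
iso-surface at level 0 with a marching-tetrahedra tessellation. On digitized
spheres of radius ≥ 10 voxels and parotid-scale ellipsoids this is accurate
to better than 1%. The trade-off is deliberate: the smoothing rounds *sharp
edges*, so the surface of a sharply-cornered cube is underestimated by about
13%. Anatomical ROIs have no sharp edges; accuracy on smooth convex bodies
was chosen over accuracy on polyhedra. Sub-voxel-thin ROIs that vanish under
smoothing fall back to the exposed voxel-face area so the value stays
positive and finite.

## Variable selection

Selection runs separately for the geometric and the intensity/texture family,
per week, on z-score-normalised deltas (mean 0, SD 1 across patients;
zero-variance columns are dropped with a warning):

1. **Correlation prefilter.** For every pair with |Pearson r| > 0.80 only the
   feature with the larger univariable log-likelihood improvement against the
   endpoint is kept. The published description does not fix an order of pair
   resolution; the package resolves pairs greedily in descending |r|,
   skipping pairs whose loser is already removed, which makes the filter
   deterministic.
2. **Forward selection.** Starting from the intercept-only model, the
   candidate with the smallest likelihood-ratio-test p-value enters while
   that p-value is below 0.01. The LRT is used both for ranking and for the
   entry decision (the published text names the LRT only for entry; using
   Wald for ranking would change nothing material). Ties are broken by the
   larger absolute univariable coefficient, then lexicographically. A
   candidate whose trial fit separates completely (easy at bootstrap sample
   sizes near 50) is skipped at that step rather than accepted with a
   divergent coefficient — this stabilises the frequency counts.
3. **Bootstrap.** The whole procedure (normalisation included) is repeated on
   resamples drawn with replacement; resamples with a single outcome class
   are redrawn. Per-feature selection counts over the replicates measure
   stability. The count table is a pure function of data and seed.

## Internal validation and optimism correction

`internal_validate()` implements the classic bootstrap validation of a whole
model-*building* procedure: the procedure (including any selection) is re-run
on every resample; each bootstrap model is scored on its own resample
(apparent) and on the original data (test); the mean difference is the
optimism, subtracted from the original apparent performance. Metrics: AUC
(Mann–Whitney with ties counted half), Nagelkerke R², discrimination slope
(mean predicted risk in events minus non-events), and the Hosmer–Lemeshow
test (risk deciles by quantile, tied predictions kept together, df = groups −
2, zero-expected-count groups merged).

The published description of coefficient correction — averaging "linear
predictor slopes and intercepts" over the selection bootstrap — is a
two-sentence summary; the package implements its standard reading: for each
bootstrap model, the logistic recalibration slope of its linear predictor on
the original data is computed; the original coefficients are multiplied by
the mean slope (shrinkage), and the intercept is refit with the shrunken
slopes held fixed as an offset. Whether the original publication refit the
intercept or shrank it directly is not decidable from the text; refitting is
the variant that keeps the mean predicted risk calibrated. For the reference
(pre-treatment) model no selection is repeated inside the bootstrap, matching
the published footnote.

Wald 95% intervals are used for odds ratios, and the χ² reference without
small-sample correction for LRTs; the source text is silent on both.

## The synthetic cohort

`cohort_config()` defines the study conditions; `generate_cohort()` draws
them. Per patient:

* mean contralateral gland dose ~ N(20, 12²) Gy, truncated to [1, 75] —
  a realistic contralateral mean-dose scale for parotid-sparing IMRT/VMAT;
* baseline xerostomia ~ Bernoulli(0.38), the prevalence reported for the
  published cohort table;
* a parotid-like ROI: a voxelized ellipsoid (semi-axes 20 x 14 x 28 mm,
  ~33 cm³, per-patient size jitter ±8%) with a smooth low-order random
  deformation (amplitude 0.10) *and* fine-scale random boundary texture with
  per-patient amplitude uniform in [0.02, 0.10] of the radius;
* weekly fractional volume change `0.001 * dose + N(0, 0.033)`, floored at
  -5% (mild transient growth — oedema — is physiologic and keeps the noise
  zero-mean), applied by thresholding the smoothed internal distance
  transform (smooth erosion preserves the single-component topology that
  morphological erosion can break; growth ranks background voxels on the
  signed distance field), with a mild random directional bias (SD 0.5) so
  the gland flattens as it shrinks;
* CT-like intensities: mean 45 HU, correlated Gaussian texture (SD 12 HU,
  correlation length 1.5 voxels), distinct background, and an 80 HU contrast
  offset on the planning scan only;
* outcome: Bernoulli with logit equal to the published model-2 coefficients
  (−4.515, 2.591, 0.072/Gy, −0.481/cm²) applied to the *measured* week-3
  surface change of the generated masks. Weekly acute xerostomia follows a
  second logistic link on dose and baseline status; the 6-month endpoint
  shifts the 12-month linear predictor by +0.55 to reproduce its higher
  prevalence.

Two generator design points deserve emphasis:

* **Surface–volume decoupling.** Purely radial erosion of a smooth template
  makes surface change an almost deterministic function of volume change
  (correlation ≈ 0.995), which is unrealistic — the published cohort reports
  0.79–0.93 — and it makes the volume delta an un-distinguishable proxy of
  the surface delta. The per-patient boundary texture provides the missing
  degree of freedom: erosion planes rough boundaries preferentially, so
  rough-gland patients lose much more surface per unit volume than
  smooth-gland patients. With the default settings the week-3 surface–volume
  delta correlation is ≈ 0.89, the median week-3 surface change ≈ −3.5 cm²
  (published magnitude 2.73), the standardized week-3 surface effect is
  ≈ 1.2 (univariable p ≈ 0.001 at n = 68, the published strength), and the
  dose–shrinkage R² is weak and rises with week (≈ 0.07 at week 2 to ≈ 0.27
  at week 6). These defaults were calibrated once against those published
  anchors — the correlation band, the median reduction scale, the
  univariable significance, and the weak-but-growing dose link — and are not
  tuned further.
* **What the generator does not emulate.** No bone/air anatomy, no real
  delineation or deformable-registration error, no 3D dose distribution
  (dose is the scalar mean only, as in the published models), no ipsilateral
  gland, no DICOM. Passing tests on this cohort demonstrates that the
  *pipeline* recovers a known truth under realistic correlation structure —
  not that the published clinical coefficients would replicate in new
  patients.

`simulate_clinical_cohort()` is the generator's analytic tabular surrogate
(the same latent dose/shrinkage/outcome model with the ellipsoid surface
formula in place of voxel meshes) for large-n recovery and calibration
checks where image synthesis would be waste.

## The orchestrated study

`run_full_analysis()` reproduces the complete design: the cohort (default 68
patients) is split by enrolment order into 80% training / 20% test — 54/14
at n = 68 (the source reports the training set inconsistently as 54 and as
56 patients in different places; the package follows the 80% split rule);
bootstrap selection and the univariable scans run on the training set only
(a leakage-guard test asserts that scrambling test-set outcomes changes no
training-stage artefact); the three NTCP models are fitted on the training
set, evaluated on both sets, and the delta-feature's added value is measured
by an LRT against the pre-treatment model. Final coefficients are refit on
the entire cohort and corrected for optimism by the full
selection-inclusive bootstrap. Week 3 is the default multivariable week as a
config knob (`multivariable_week`), not a hard-coded constant, since the
original choice was empirical. Reports include per-week selection
frequencies, univariable scans, Wilson-interval incidence curves split at
the median week-3 surface change, and per-week dose-vs-delta regressions.

Age and sex are not simulated or modelled: the source screened and excluded
them as non-significant, and they carry no information in a generator that
does not produce them.

## Numerical choices and problem sizes

* Logistic fits: IRLS via `stats::glm` with convergence tolerance 1e-10 and
  a 100-iteration cap; separation is detected (fitted probabilities within
  1e-8 of 0/1 or |coefficient| > 30 on the working scale) and reported as an
  error naming the predictor, or as a skip/flag inside selection scans.
* Seeds: every stochastic component takes an explicit seed; child seeds are
  derived arithmetically and kept within the 32-bit integer range. Identical
  config + seed reproduces cohorts, counts and reports bit-for-bit.
* The test suite and the acceptance script run the bootstrap stages at 200
  replicates and the recovery checks at n = 2000 over 100 seeds; these sizes
  keep Monte-Carlo error comfortably inside the asserted tolerances. The
  package default for `n_bootstrap` and `validation_B` remains 1000, the
  published replicate count.

## Known limitations

* The mesh surface estimator is tuned for smooth anatomical shapes; it is
  biased low on polyhedral phantoms with sharp edges (see above).
* Delta tables assume one scan per week index; repeated scans per week are
  out of scope.
* The generator's intensity model is stationary Gaussian texture — adequate
  for exercising texture-feature code paths, but not a claim about real CT
  noise; intensity/texture deltas in the synthetic cohort carry no outcome
  signal by construction, mirroring the published finding that none were
  significant.
* Only the contralateral gland is modelled; laterality handling beyond that
  is out of scope.
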